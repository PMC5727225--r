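#' Named parameter presets
#'
#' Returns a ready [sim_config()] for a named study design:
#' \describe{
#'   \item{`baseline`}{the standard coevolution parameterisation: b_x = 1,
#'     d_x = 0.1, mu_x = 1e-4, r_c = 5e-5, d_y = 0.5, mu_y = 1e-3,
#'     p = 0.005, m = 3, k_max = 0.3; 1000 prey at g = 1 and 100 predators
#'     at k = k_max; horizon 2000.}
#'   \item{`diversity-sweep`}{identical rates; intended for sweeps over
#'     `m` with [run_sweep()].}
#'   \item{`prey-only`}{the "evolution of only prey" scenario: mu_y = 0
#'     and `predator_evolves = FALSE`, naive ancestor predator fixed at
#'     k_max.}
#' }
#' Overrides are supplied as `key = value` pairs and may address any
#' [coevo_params()] field or any [sim_config()] field; unknown keys are
#' rejected.
#'
#' @param name preset name.
#' @param ... overrides, e.g. `m = 10`, `r_c = 5e-4`, `t_max = 500`.
#' @return A validated `coevo_config`.
#' @examples
#' coevo_preset("baseline", m = 10, t_max = 200)
#' @export
coevo_preset <- function(name = c("baseline", "diversity-sweep", "prey-only"), ...) {
  name <- match.arg(name)
  par_args <- list()
  if (identical(name, "prey-only"))
    par_args <- list(mu_y = 0, predator_evolves = FALSE)
  apply_overrides(do.call(coevo_params, par_args), list(...))
}

#' @rdname coevo_preset
#' @export
preset_names <- function() c("baseline", "diversity-sweep", "prey-only")

# split overrides between parameter fields and config fields, validate keys
apply_overrides <- function(params, overrides,
                            t_max = 2000, sample_dt = 1.0, seed = 1L) {
  par_keys <- setdiff(names(formals(coevo_params)), "...")
  cfg_keys <- setdiff(names(formals(sim_config)), c("params", "..."))
  cfg_args <- list(t_max = t_max, sample_dt = sample_dt, seed = seed)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named key = value pairs", call. = FALSE)
    for (key in names(overrides)) {
      if (key %in% par_keys) params[[key]] <- overrides[[key]]
      else if (key %in% cfg_keys) cfg_args[[key]] <- overrides[[key]]
      else stop("unknown configuration key '", key, "'", call. = FALSE)
    }
  }
  params <- do.call(coevo_params, unclass(params))
  do.call(sim_config, c(list(params = params), cfg_args))
}

#' Read and write simulation configurations as YAML
#'
#' A configuration is serialised as a flat YAML map: every
#' [coevo_params()] field plus the [sim_config()] fields (`t_max`,
#' `sample_dt`, `seed`, initial condition, `stop_on_total_extinction`).
#' `load_config()` accepts either a file path or a preset name and applies
#' `key = value` overrides on top.
#'
#' @param config a `coevo_config`.
#' @param path file path.
#' @param ... overrides as in [coevo_preset()].
#' @return `read_config()`/`load_config()` return a validated
#'   `coevo_config`; `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "coevo_config"))
  flat <- c(unclass(config$params),
            config[setdiff(names(config), "params")])
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path, ...) {
  flat <- yaml::read_yaml(path)
  par_keys <- setdiff(names(formals(coevo_params)), "...")
  cfg_keys <- setdiff(names(formals(sim_config)), c("params", "..."))
  unknown <- setdiff(names(flat), c(par_keys, cfg_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(coevo_params, flat[intersect(names(flat), par_keys)])
  cfg <- do.call(sim_config,
                 c(list(params = params), flat[intersect(names(flat), cfg_keys)]))
  apply_overrides(cfg$params, list(...),
                  t_max = cfg$t_max, sample_dt = cfg$sample_dt, seed = cfg$seed)
}

#' @rdname write_config
#' @param x a file path or a preset name.
#' @export
load_config <- function(x, ...) {
  if (file.exists(x)) read_config(x, ...)
  else if (x %in% preset_names()) coevo_preset(x, ...)
  else stop("'", x, "' is neither an existing file nor a known preset",
            call. = FALSE)
}

# stable short hash of the configuration (polynomial rolling hash of its
# YAML text; a label for artifact provenance, not cryptographic)
config_hash <- function(config) {
  s <- yaml::as.yaml(c(unclass(config$params),
                       config[setdiff(names(config), "params")]))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write and read a trajectory as tidy delimited text
#'
#' The samples file holds one row per sample time per extant type
#' (`t`, `species`, `type_id`, `trait`, `count`, tab-separated); the
#' genealogy file holds one row per type ever created (`species`, `id`,
#' `parent_id`, `trait`, `t_origin`, `t_extinct`). Both start with `#`
#' comment lines embedding the seed, terminal status, event tallies,
#' configuration hash and the full configuration in YAML, so every
#' artifact is reproducible from its own header. `read_trajectory()`
#' reconstructs a full `coevo_trajectory` from the pair.
#'
#' @param traj a [coevo_sim()] trajectory.
#' @param file samples file path.
#' @param genealogy_file genealogy file path; defaults to
#'   `<file>.genealogy.tsv`.
#' @return `write_trajectory()` returns `file` invisibly;
#'   `read_trajectory()` returns a `coevo_trajectory`.
#' @export
write_trajectory <- function(traj, file,
                             genealogy_file = paste0(file, ".genealogy.tsv")) {
  stopifnot(inherits(traj, "coevo_trajectory"))
  cfg <- traj$config
  meta <- c(list(seed = traj$seed, status = traj$status,
                 n_events = traj$n_events,
                 config_hash = config_hash(cfg),
                 tallies = as.list(traj$tallies)),
            list(config = c(unclass(cfg$params),
                            cfg[setdiff(names(cfg), "params")])))
  header <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])

  long_rows <- function(mat, species) {
    gen <- traj$genealogy[traj$genealogy$species == species, ]
    idx <- which(mat > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    ids <- as.integer(colnames(mat))[idx[, 2]]
    data.frame(t = traj$times[idx[, 1]], species = species, type_id = ids,
               trait = gen$trait[match(ids, gen$id)],
               count = mat[idx])
  }
  d <- rbind(long_rows(traj$prey, "prey"), long_rows(traj$predator, "predator"))
  d <- d[order(d$t, d$species, d$type_id), ]
  writeLines(header, file)
  suppressWarnings(write.table(d, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  writeLines(header, genealogy_file)
  suppressWarnings(write.table(traj$genealogy, genealogy_file, sep = "\t",
                               quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file,
                            genealogy_file = paste0(file, ".genealogy.tsv")) {
  hdr <- grep("^#", readLines(file), value = TRUE)
  meta <- yaml::yaml.load(paste(sub("^# ?", "", hdr), collapse = "\n"))
  flat <- meta$config
  params <- do.call(coevo_params,
                    flat[intersect(names(flat),
                                   setdiff(names(formals(coevo_params)), "..."))])
  cfg_keys <- setdiff(names(formals(sim_config)), c("params", "..."))
  config <- do.call(sim_config,
                    c(list(params = params),
                      flat[intersect(names(flat), cfg_keys)]))
  d <- read.delim(file, comment.char = "#")
  gen <- read.delim(genealogy_file, comment.char = "#")
  times <- seq(0, config$t_max, by = config$sample_dt)
  rebuild <- function(species) {
    ids <- gen$id[gen$species == species]
    m <- matrix(0L, nrow = length(times), ncol = length(ids))
    if (length(ids)) colnames(m) <- ids
    dd <- d[d$species == species, ]
    if (nrow(dd))
      m[cbind(match(round(dd$t, 9), round(times, 9)),
              match(dd$type_id, ids))] <- dd$count
    m
  }
  structure(list(times = times, prey = rebuild("prey"),
                 predator = rebuild("predator"), genealogy = gen,
                 tallies = unlist(meta$tallies), status = meta$status,
                 n_events = meta$n_events, config = config,
                 seed = meta$seed),
            class = "coevo_trajectory")
}

#' Read and write growth-assay tables
#'
#' Tab-separated with a documented header: `prey_pop`, `pred_pop`,
#' `prey_growth`, then one `repN` column per technical replicate.
#'
#' @param assay a `growth_assay` data frame.
#' @param path file path.
#' @return `read_assay()` returns a `growth_assay`; `write_assay()`
#'   returns `path` invisibly.
#' @export
write_assay <- function(assay, path) {
  write.table(assay, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay
#' @export
read_assay <- function(path) {
  d <- read.delim(path)
  need <- c("prey_pop", "pred_pop", "prey_growth")
  if (!all(need %in% names(d)))
    stop("assay file must have columns ", paste(need, collapse = ", "),
         " and rep1, rep2, ...", call. = FALSE)
  class(d) <- c("growth_assay", "data.frame")
  d
}
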