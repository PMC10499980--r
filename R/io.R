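# Configuration loading, presets and result serialisation for script and
# command-line use.  Presets store the dimensional physiology; every
# dimensionless quantity is derived at load time so that Table-style
# derived values are always recomputed from the primaries.

.config_keys <- c("preset", "mutant", "plasmodesmata", "physiology",
                  "geometry", "profile", "solver", "output")
.physiology_keys <- c("pK", "pH_apo", "pH_cyt", "pH_vac", "V_mem", "V_ton",
                      "T_abs", "P_pass", "P_imp", "P_exp", "P_plas",
                      "D_apo", "C_up")
.geometry_keys <- c("n_cells", "width_um", "apoplast_um", "length_um",
                    "fraction")
.profile_keys <- c("kind", "kappa", "phi0", "vacuolar_expansion", "alpha",
                   "nu", "phi1", "phiN1", "T_div", "l1_um", "lN1_um")

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a transport run: either
#' a `preset` (`ga_short`, `ga_long`) optionally combined with `mutant`
#' and `plasmodesmata` overrides, or explicit `physiology` and `geometry`
#' blocks, plus an optional `profile` block.  Unknown keys are rejected,
#' and the provenance of every top-level choice (preset versus override)
#' is recorded.
#'
#' @param path Path to a YAML/JSON file.
#' @return List of class `run_config` with `params` (a `cell_params`),
#'   optional `profile`, `solver` and `output` lists, and a `provenance`
#'   character vector.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || !length(cfg))
    stop("empty config; required: 'preset' or 'physiology' + 'geometry'")
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  prov <- character(0)

  mutant <- cfg$mutant %||% "wild_type"
  plas <- cfg$plasmodesmata %||% TRUE
  if (!is.null(cfg$preset)) {
    preset <- match.arg(cfg$preset, c("ga_short", "ga_long"))
    phys <- gaPhysiology()
    geom <- gaGeometry(if (preset == "ga_short") "short" else "long")
    prov <- c(prov, paste0("physiology/geometry from preset ", preset))
  } else {
    if (is.null(cfg$physiology) || is.null(cfg$geometry))
      stop("config needs 'preset' or both 'physiology' and 'geometry'; ",
           "required physiology keys: ",
           paste(setdiff(.physiology_keys, "C_up"), collapse = ", "))
    badp <- setdiff(names(cfg$physiology), .physiology_keys)
    if (length(badp)) stop("unknown physiology keys: ",
                           paste(badp, collapse = ", "))
    badg <- setdiff(names(cfg$geometry), .geometry_keys)
    if (length(badg)) stop("unknown geometry keys: ",
                           paste(badg, collapse = ", "))
    phys <- do.call(hormonePhysiology, cfg$physiology)
    geom <- cellFileGeometry(cfg$geometry$n_cells, cfg$geometry$width_um,
                             cfg$geometry$apoplast_um,
                             cfg$geometry$length_um, cfg$geometry$fraction)
    prov <- c(prov, "physiology/geometry explicit")
  }
  if (!is.null(cfg$mutant)) prov <- c(prov, paste0("mutant override: ", mutant))
  if (!is.null(cfg$plasmodesmata))
    prov <- c(prov, paste0("plasmodesmata override: ", plas))

  params <- nondimensionalize(phys, geom, mutant = mutant,
                              plasmodesmata = plas)

  profile <- NULL
  if (!is.null(cfg$profile)) {
    badk <- setdiff(names(cfg$profile), .profile_keys)
    if (length(badk)) stop("unknown profile keys: ",
                           paste(badk, collapse = ", "))
    pr <- cfg$profile
    profile <- switch(pr$kind,
      static_uniform = staticUniformProfile(pr$phi0 %||% geom$fractions[1]),
      linear_time = linearTimeProfile(pr$kappa,
                                      pr$phi0 %||% geom$fractions[1],
                                      pr$vacuolar_expansion %||% TRUE),
      linear_space = {
        if (!is.null(pr$l1_um)) {
          fit <- fitLinearFile(pr$l1_um, pr$lN1_um, pr$phi1, pr$phiN1,
                               N = geom$N, a = geom$a)
          params <- nondimensionalize(phys, fit$geometry, mutant = mutant,
                                      plasmodesmata = plas)
          fit$profile
        } else linearSpaceProfile(pr$alpha, pr$nu, pr$phi1, pr$phiN1)
      },
      exponential_division = divisionProfile(
        divisionSchedule(pr$T_div, params$lambda),
        pr$phi0 %||% 0.1),
      stop("unknown profile kind: ", pr$kind))
    prov <- c(prov, paste0("profile: ", pr$kind))
  }

  structure(list(params = params, profile = profile,
                 solver = cfg$solver, output = cfg$output,
                 provenance = prov),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write model results to CSV and JSON
#'
#' Serialises a trajectory or a coefficient set.  Trajectories
#' ([simulateDiscrete()] output) become long-format CSV with columns
#' `time`, `cell`, `compartment`, `concentration`; continuum solutions
#' become `time`, `xi`, `concentration`; coefficient lists become a JSON
#' object.  Floating point values are written with 12 significant digits
#' and deterministic column order.
#'
#' @param x A `file_trajectory`, `continuum_solution`, or named list of
#'   numeric values (e.g. from [effectiveCoefficients()]).
#' @param path Output file path; extension `.csv` or `.json` selects the
#'   format where both are possible.
#' @return `path`, invisibly.
#' @export
writeResults <- function(x, path) {
  fmt_num <- function(v) signif(v, 12)
  if (inherits(x, "file_trajectory")) {
    comp <- c("c", "v", "f", "g", "h")
    df <- do.call(rbind, lapply(comp, function(s) {
      m <- x[[s]]
      data.frame(time = rep(x$t, times = ncol(m)),
                 cell = rep(seq_len(ncol(m)), each = nrow(m)),
                 compartment = s,
                 concentration = fmt_num(as.vector(m)))
    }))
    df <- df[order(df$time, df$cell, df$compartment), ]
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "continuum_solution")) {
    df <- data.frame(time = rep(x$t, times = length(x$xi)),
                     xi = rep(x$xi, each = length(x$t)),
                     concentration = fmt_num(as.vector(x$C)))
    df <- df[order(df$time, df$xi), ]
    utils::write.csv(df, path, row.names = FALSE)
  } else if (is.list(x)) {
    keep <- vapply(x, is.numeric, logical(1))
    jsonlite::write_json(lapply(x[keep], fmt_num), path,
                         auto_unbox = TRUE, digits = NA)
  } else stop("unsupported result type: ", class(x)[1])
  invisible(path)
}
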