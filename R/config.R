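# Run configuration: a flat TOML-style key = value text file (JSON also
# accepted). Unknown keys are rejected; omitted keys fall back to the
# published model defaults.

config_schema <- function() {
  list(
    E_matrix = "number", nu_matrix = "number", fiber_ratio = "number",
    turgor_P = "number", wall_thickness = "number", beam_fraction = "number",
    boundary_expansion = "number",
    target_h = "number", tol_rel = "number", max_iter = "number",
    seed = "number", output_dir = "string")
}

parse_toml_ish <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "" || grepl("^\\[", ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (grepl('^".*"$', val)) val <- substr(val, 2L, nchar(val) - 1L)
    else if (val %in% c("true", "false")) val <- val == "true"
    else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}

#' Load a run configuration
#'
#' Missing keys take the published model defaults (matrix modulus 40 MPa,
#' turgor 0.2 MPa, wall thickness 1 um, fiber ratio 5, boundary expansion
#' 1%, beam fraction 1/5). Unknown keys and type mismatches are errors.
#'
#' @param path config file (TOML-style `key = value` lines or JSON); `NULL`
#'   gives the pure defaults.
#' @return a `run_config` list with a `material` ([material_params()])
#'   element plus solver/meshing keys.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- readLines(path, warn = FALSE)
    if (any(grepl("^\\s*\\{", txt)))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else parse_toml_ish(txt)
  }
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(raw)) {
    want <- schema[[k]]
    ok <- switch(want,
                 number = is.numeric(raw[[k]]) && length(raw[[k]]) == 1L,
                 string = is.character(raw[[k]]) && length(raw[[k]]) == 1L)
    if (!ok) stop("config key '", k, "' must be a ", want)
  }
  get <- function(k, default) if (!is.null(raw[[k]])) raw[[k]] else default
  material <- material_params(
    E_matrix = get("E_matrix", 40),
    nu_matrix = get("nu_matrix", 0.3),
    fiber_ratio = get("fiber_ratio", 5),
    turgor_P = get("turgor_P", 0.2),
    wall_thickness = get("wall_thickness", 1),
    beam_fraction = get("beam_fraction", 1 / 5),
    boundary_expansion = get("boundary_expansion", 0.01))
  structure(list(material = material,
                 target_h = get("target_h", 2.5),
                 tol_rel = get("tol_rel", 1e-8),
                 max_iter = as.integer(get("max_iter", 200L)),
                 seed = as.integer(get("seed", 1L)),
                 output_dir = get("output_dir", ".")),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes the flat TOML-style form read back by [load_config()]; the
#' round-trip reproduces the effective configuration exactly.
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  m <- config$material
  num <- function(x) format(x, digits = 17)
  lines <- c(
    paste("E_matrix =", num(m$E_matrix)),
    paste("nu_matrix =", num(m$nu_matrix)),
    paste("fiber_ratio =", num(m$fiber_ratio)),
    paste("turgor_P =", num(m$turgor_P)),
    paste("wall_thickness =", num(m$wall_thickness)),
    paste("beam_fraction =", num(m$beam_fraction)),
    paste("boundary_expansion =", num(m$boundary_expansion)),
    paste("target_h =", num(config$target_h)),
    paste("tol_rel =", num(config$tol_rel)),
    paste("max_iter =", config$max_iter),
    paste("seed =", config$seed),
    paste0('output_dir = "', config$output_dir, '"'))
  writeLines(lines, path)
  invisible(path)
}
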