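.param_fields <- c(
  "drive_conversion_female", "drive_conversion_male",
  "germline_resistance_female", "germline_resistance_male",
  "embryo_resistance_maternal", "paternal_deposition",
  "somatic_cost_female", "somatic_cost_male", "x_shredding"
)

.preset_env <- new.env(parent = emptyenv())

.load_presets <- function() {
  if (is.null(.preset_env$presets)) {
    path <- system.file("extdata", "drive_presets.json", package = "drivesim")
    .preset_env$presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .preset_env$presets
}

#' Drive parameterisations
#'
#' The nine shipped drive parameter sets: two interpretations of the
#' zpg-promoter homing drive (`zpg` with paternal Cas9 deposition, `zpg2`
#' without it but with a higher female somatic fitness cost), the same two
#' with an added X-shredder (`zpgX`, `zpg2X`), four interpretations of the
#' nos-promoter drive differing in somatic fitness costs (`nos`, `nosF`,
#' `nosF2`, `nosF3`), and an inert `wildtype` control with every rate zero.
#'
#' @return A tibble with one row per preset and one column per rate.
#' @seealso [drive_params()]
#' @export
#' @examples
#' drive_presets()
drive_presets <- function() {
  p <- .load_presets()
  dplyr::bind_cols(
    tibble::tibble(drive = names(p)),
    dplyr::bind_rows(lapply(p, tibble::as_tibble))
  )
}

#' Construct or look up a drive parameter set
#'
#' Either give a preset name (see [drive_presets()]) or any subset of the
#' rate fields to override. All rates are probabilities or cost fractions
#' in \[0, 1\].
#'
#' @param drive Preset name, or `NULL` to start from all-zero rates.
#' @param ... Named overrides of individual fields, e.g.
#'   `somatic_cost_female = 0.2`.
#' @return A `drive_params` object (named list of the nine rates).
#' @export
#' @examples
#' drive_params("zpg")
#' drive_params("nosF3", x_shredding = 0.5)
drive_params <- function(drive = NULL, ...) {
  if (inherits(drive, "drive_params")) {
    base <- unclass(drive)
    nm <- attr(drive, "drive")
  } else if (is.null(drive)) {
    base <- as.list(stats::setNames(rep(0, length(.param_fields)), .param_fields))
    nm <- "custom"
  } else {
    stopifnot(is.character(drive), length(drive) == 1)
    presets <- .load_presets()
    if (!drive %in% names(presets)) {
      stop("unknown drive preset '", drive, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    base <- as.list(presets[[drive]])
    nm <- drive
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .param_fields)
    if (length(bad)) stop("unknown drive parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    base <- modifyList(base, dots)
    nm <- "custom"
  }
  vals <- unlist(base[.param_fields])
  if (any(vals < 0 | vals > 1)) {
    stop("all drive parameters must lie in [0, 1]", call. = FALSE)
  }
  structure(base[.param_fields], class = "drive_params", drive = nm)
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params:", attr(x, "drive"), ">\n")
  for (f in .param_fields) cat(sprintf("  %-28s %g\n", f, x[[f]]))
  invisible(x)
}

# normalize user input (name or drive_params) to a drive_params object
.as_params <- function(drive) {
  if (inherits(drive, "drive_params")) drive else drive_params(drive)
}

# TRUE when the parameter set is a real construct (anything non-zero);
# the wildtype control has no drive to release
.is_inert <- function(params) all(unlist(params) == 0)
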