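#' Van der Waals radii table with solvent probe
#'
#' A radii table maps heavy-atom elements to van der Waals radii and carries
#' the solvent probe radius added to every atom when tracing the accessible
#' surface. Defaults are the Chothia united-atom values with a 1.4 Angstrom
#' water probe.
#'
#' @param values named numeric vector of radii in Angstrom; names are element
#'   symbols (C, N, O, S after hydrogen stripping)
#' @param probe probe radius in Angstrom (water: 1.4)
#' @return an object of class `radii_table`
#' @export
#' @examples
#' radii_table()
#' radii_table(probe = 0)  # bare van der Waals surface
radii_table <- function(values = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85),
                        probe = 1.4) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("radii values must be named by element symbol", call. = FALSE)
  if (any(values <= 1.0 | values >= 2.5))
    stop("van der Waals radii must lie in (1.0, 2.5) Angstrom", call. = FALSE)
  if (length(probe) != 1L || is.na(probe) || probe < 0)
    stop("probe radius must be a single non-negative number", call. = FALSE)
  structure(list(values = values, probe = probe), class = "radii_table")
}

#' Read a radii table from a `key: value` config file
#'
#' The file holds one `element: radius` pair per line plus an optional
#' `probe: <r>` line; `#` comments and blank lines are ignored.
#'
#' @param path file path
#' @return a [radii_table()]
#' @export
read_radii <- function(path) {
  if (!file.exists(path)) stop("radii file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  probe <- if (!is.null(cfg$probe)) as.numeric(cfg$probe) else 1.4
  cfg$probe <- NULL
  radii_table(values = unlist(cfg), probe = probe)
}

#' @export
print.radii_table <- function(x, ...) {
  cat("radii_table:",
      paste(names(x$values), format(x$values), sep = "=", collapse = " "),
      sprintf("probe=%.2f\n", x$probe))
  invisible(x)
}

atom_radius <- function(element, radii) {
  stopifnot(inherits(radii, "radii_table"))
  r <- radii$values[element]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}
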