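# Monoisotopic masses (CODATA/IUPAC 2021) used to assemble adduct deltas.
.MASS <- list(
  e  = 0.000548579909,
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928,
  Cl = 34.96885268,
  K  = 38.9637064864
)

.adduct_delta <- function(add, remove = 0, charge = 1L) {
  # m/z delta for a singly charged species: atoms added minus atoms removed,
  # minus one electron per positive charge (plus one per negative charge)
  add - remove - sign(charge) * .MASS$e
}

#' Built-in adduct table
#'
#' Returns the adduct species searched per polarity: positive mode
#' \{[M]+, [M+H]+, [M+Na]+, [M+NH4]+, [M+K]+\} and negative mode
#' \{[M-H]-, [M+Na-2H]-, [M+NH4-2H]-, [M+Cl]-, [M+K-2H]-, [M+FA-H]-,
#' [M+H2O-H]-\}. Mass deltas are assembled from monoisotopic atomic
#' masses with full electron-mass accounting (one electron per unit charge),
#' all species singly charged.
#'
#' The chloride species is chemically a chloride attachment [M+Cl]-;
#' \code{chloride = "literal"} instead subtracts a chlorine ([M-Cl]-), for
#' strict compatibility with transition lists that encode it that way.
#'
#' @param polarity "positive", "negative" or "both".
#' @param chloride "attach" (default, [M+Cl]-) or "literal" ([M-Cl]-).
#' @return data.frame with columns name, polarity, mass_delta, charge.
#' @export
adduct_table <- function(polarity = c("both", "positive", "negative"),
                         chloride = c("attach", "literal")) {
  polarity <- match.arg(polarity)
  chloride <- match.arg(chloride)
  m <- .MASS
  nh4 <- m$N + 4 * m$H
  fa  <- m$C + 2 * m$H + 2 * m$O        # formic acid HCOOH
  h2o <- 2 * m$H + m$O
  pos <- data.frame(
    name = c("[M]+", "[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+"),
    polarity = "positive",
    mass_delta = c(
      .adduct_delta(0) + m$e,           # [M]+ kept at exactly zero delta
      .adduct_delta(m$H),
      .adduct_delta(m$Na),
      .adduct_delta(nh4),
      .adduct_delta(m$K)
    ),
    charge = 1L,
    stringsAsFactors = FALSE
  )
  cl_name  <- if (chloride == "attach") "[M+Cl]-" else "[M-Cl]-"
  cl_delta <- if (chloride == "attach") {
    .adduct_delta(m$Cl, charge = -1L)
  } else {
    .adduct_delta(0, m$Cl, charge = -1L)
  }
  neg <- data.frame(
    name = c("[M-H]-", "[M+Na-2H]-", "[M+NH4-2H]-", cl_name,
             "[M+K-2H]-", "[M+FA-H]-", "[M+H2O-H]-"),
    polarity = "negative",
    mass_delta = c(
      .adduct_delta(0, m$H, charge = -1L),
      .adduct_delta(m$Na, 2 * m$H, charge = -1L),
      .adduct_delta(nh4, 2 * m$H, charge = -1L),
      cl_delta,
      .adduct_delta(m$K, 2 * m$H, charge = -1L),
      .adduct_delta(fa, m$H, charge = -1L),
      .adduct_delta(h2o, m$H, charge = -1L)
    ),
    charge = -1L,
    stringsAsFactors = FALSE
  )
  switch(polarity, positive = pos, negative = neg, both = rbind(pos, neg))
}

#' Read an adduct table from CSV
#'
#' Expects columns name, polarity, mass_delta and optionally charge;
#' an editable alternative to the built-in \code{\link{adduct_table}}.
#'
#' @param path CSV file path.
#' @return data.frame as from \code{\link{adduct_table}}.
#' @export
read_adduct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "polarity", "mass_delta")
  if (!all(need %in% names(tab)))
    stop("adduct CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$charge))
    tab$charge <- ifelse(tab$polarity == "positive", 1L, -1L)
  if (any(!is.finite(tab$mass_delta))) stop("non-finite mass_delta in adduct table")
  tab
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' @param neutral_mass neutral monoisotopic mass in Da (> 0).
#' @param adduct adduct name (e.g. "[M+H]+") looked up in \code{adducts},
#'   or a single row of an adduct table.
#' @param adducts adduct table (default \code{\link{adduct_table}("both")}).
#' @return m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct, adducts = adduct_table("both")) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  if (is.character(adduct)) {
    i <- match(adduct, adducts$name)
    if (is.na(i)) stop("unknown adduct name: ", adduct)
    delta <- adducts$mass_delta[i]
  } else {
    delta <- adduct$mass_delta
  }
  neutral_mass + delta
}

#' SWATH isolation-window scheme
#'
#' Contiguous fixed-width windows tiling [start, end); the default is the
#' 50-1100 Da range cut into 21 windows of 50 Da. Window indices are 0-based:
#' [50,100) is window 0. The last window's upper edge is closed so that
#' mz = end is assignable.
#'
#' @param start,end acquisition range in Da.
#' @param width window width in Da.
#' @return object of class "swath_scheme" with a windows matrix (lo, hi).
#' @export
swath_scheme <- function(start = 50, end = 1100, width = 50) {
  stopifnot(end > start, width > 0)
  nwin <- ceiling((end - start) / width - 1e-9)
  lo <- start + width * (seq_len(nwin) - 1)
  hi <- pmin(lo + width, end)
  structure(
    list(start = start, end = end, width = width,
         windows = cbind(lo = lo, hi = hi)),
    class = "swath_scheme"
  )
}

#' @export
print.swath_scheme <- function(x, ...) {
  cat(sprintf("SWATH scheme: %g-%g Da, %d windows of %g Da\n",
              x$start, x$end, nrow(x$windows), x$width))
  invisible(x)
}

#' @export
format.swath_scheme <- function(x, ...)
  sprintf("swath_scheme(%g, %g, %g)", x$start, x$end, x$width)

n_windows <- function(scheme) nrow(scheme$windows)

#' Assign an m/z to its SWATH window
#'
#' Half-open convention: mz on a window boundary belongs to the upper window;
#' mz equal to the scheme end belongs to the last window. Indices are 0-based.
#'
#' @param mz m/z values in Da (vectorised).
#' @param scheme a \code{\link{swath_scheme}}.
#' @return integer window indices.
#' @export
assign_window <- function(mz, scheme = swath_scheme()) {
  if (any(mz < scheme$start | mz > scheme$end))
    stop(sprintf("m/z outside acquisition range [%g, %g]",
                 scheme$start, scheme$end))
  idx <- as.integer(floor((mz - scheme$start) / scheme$width))
  pmin(idx, nrow(scheme$windows) - 1L)
}

#' Symmetric ppm tolerance window around an m/z
#'
#' @param mz m/z in Da.
#' @param ppm tolerance in parts per million.
#' @return numeric c(lo, hi) in Da (a 2-column matrix for vector input).
#' @export
ppm_window <- function(mz, ppm) {
  stopifnot(all(mz > 0), all(ppm >= 0))
  lo <- mz * (1 - ppm * 1e-6)
  hi <- mz * (1 + ppm * 1e-6)
  if (length(mz) == 1L) c(lo = lo, hi = hi) else cbind(lo = lo, hi = hi)
}
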