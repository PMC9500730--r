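# Spectral-library parsing and curation into the DIA transition database.
#
# Curation chain per spectrum: normalize_relative -> tag_and_filter ->
# collapse_near_duplicates -> build_dia_entry. Fragments are tagged D (main
# daughter) above the 75% relative-intensity threshold and F (secondary)
# between 5% and 75%; below 5% they are excluded as noise-level transitions.

#' One acquired MS/MS library record
#'
#' @param splash_id spectral-hash identifier (opaque grouping key, kept
#'   verbatim).
#' @param compound_id,compound_name compound accession and display name.
#' @param neutral_mass neutral monoisotopic mass in Da (> 0).
#' @param polarity "positive" or "negative".
#' @param fragments data.frame with columns mz (Da, > 0) and intensity
#'   (raw counts, >= 0); must be non-empty.
#' @param resolution "high" or "low".
#' @param collision_energy collision energy in eV, or NA when unknown.
#' @return object of class "library_spectrum".
#' @export
library_spectrum <- function(splash_id, compound_id, compound_name,
                             neutral_mass, polarity, fragments,
                             resolution = "high", collision_energy = NA_real_) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  resolution <- match.arg(resolution, c("high", "low"))
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1L ||
      !is.finite(neutral_mass) || neutral_mass <= 0)
    stop("neutral_mass must be a single positive number")
  fragments <- as.data.frame(fragments)
  if (nrow(fragments) == 0L) stop("fragments must be non-empty")
  if (!all(c("mz", "intensity") %in% names(fragments)))
    stop("fragments need columns mz and intensity")
  if (any(fragments$mz <= 0)) stop("fragment m/z must be > 0")
  if (any(fragments$intensity < 0)) stop("fragment intensity must be >= 0")
  structure(
    list(splash_id = as.character(splash_id),
         compound_id = as.character(compound_id),
         compound_name = as.character(compound_name),
         neutral_mass = neutral_mass, polarity = polarity,
         resolution = resolution, collision_energy = collision_energy,
         fragments = fragments[, c("mz", "intensity")]),
    class = "library_spectrum"
  )
}

#' @export
print.library_spectrum <- function(x, ...) {
  cat(sprintf("<library_spectrum> %s (%s), M = %.5f Da, %s mode, %d fragments\n",
              x$compound_name, x$splash_id, x$neutral_mass, x$polarity,
              nrow(x$fragments)))
  invisible(x)
}

.spectrum_field_map <- c(
  splash_id = "splash_id", splash = "splash_id",
  compound_id = "compound_id", compound_name = "compound_name",
  name = "compound_name", neutral_mass = "neutral_mass",
  exactmass = "neutral_mass", mw = "neutral_mass",
  polarity = "polarity", ionmode = "polarity",
  resolution = "resolution", collision_energy = "collision_energy",
  collisionenergy = "collision_energy"
)

.norm_polarity <- function(x) {
  x <- tolower(as.character(x))
  if (x %in% c("positive", "pos", "p", "+")) return("positive")
  if (x %in% c("negative", "neg", "n", "-")) return("negative")
  stop("unrecognised polarity: ", x)
}

.record_to_spectrum <- function(rec, idx) {
  tryCatch(
    library_spectrum(
      splash_id = rec$splash_id, compound_id = rec$compound_id,
      compound_name = rec$compound_name,
      neutral_mass = as.numeric(rec$neutral_mass),
      polarity = .norm_polarity(rec$polarity),
      fragments = rec$fragments,
      resolution = if (is.null(rec$resolution)) "high" else tolower(rec$resolution),
      collision_energy = if (is.null(rec$collision_energy)) NA_real_
                         else suppressWarnings(as.numeric(rec$collision_energy))
    ),
    error = function(e) stop(sprintf("record %d: %s", idx, conditionMessage(e)),
                             call. = FALSE)
  )
}

.parse_msp_blocks <- function(lines) {
  lines <- sub("\r$", "", lines)
  starts <- grep("^\\s*NAME\\s*:", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no NAME: fields found; not MSP?")
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(b) {
    blk <- lines[starts[b]:ends[b]]
    kv_idx <- grep("^\\s*[A-Za-z_][A-Za-z_ 0-9]*\\s*:", blk)
    rec <- list()
    for (i in kv_idx) {
      key <- tolower(gsub("\\s+", "_", trimws(sub(":.*$", "", blk[i]))))
      val <- trimws(sub("^[^:]*:", "", blk[i]))
      if (key == "num_peaks") next
      field <- .spectrum_field_map[key]
      if (!is.na(field)) rec[[field]] <- val
    }
    peak_lines <- blk[grep("^\\s*[0-9]", blk)]
    if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[\\s;]+",
                                            perl = TRUE), function(p) {
        suppressWarnings(as.numeric(p[1:2]))
      }))
      rec$fragments <- data.frame(mz = mat[, 1], intensity = mat[, 2])
    } else {
      rec$fragments <- data.frame(mz = numeric(0), intensity = numeric(0))
    }
    if (is.null(rec$compound_id)) rec$compound_id <- rec$compound_name
    rec
  })
}

#' Parse spectral-library records
#'
#' Reads MS/MS library records from one of three dialects:
#' \describe{
#'   \item{msp}{NIST-style blocks: \code{NAME:}, \code{SPLASH:},
#'     \code{EXACTMASS:} (or \code{MW:}), \code{IONMODE:}, optional
#'     \code{COMPOUND_ID:}, \code{RESOLUTION:}, \code{COLLISIONENERGY:},
#'     \code{Num Peaks:} then one "mz intensity" pair per line.}
#'   \item{csv}{long table, one row per fragment, columns splash_id,
#'     compound_id, compound_name, neutral_mass, polarity, fragment_mz,
#'     fragment_intensity (optional resolution, collision_energy).}
#'   \item{json}{array of objects with the library_spectrum fields and a
#'     fragments array of \{mz, intensity\} objects.}
#' }
#' Records with zero fragments are dropped with a warning naming them.
#'
#' @param source file path (or character vector of lines for msp).
#' @param dialect "msp", "csv" or "json".
#' @return list of \code{\link{library_spectrum}} objects.
#' @export
parse_spectra <- function(source, dialect = c("msp", "csv", "json")) {
  dialect <- match.arg(dialect)
  recs <- switch(dialect,
    msp = {
      lines <- if (length(source) == 1L && file.exists(source))
        readLines(source, warn = FALSE) else as.character(source)
      .parse_msp_blocks(lines)
    },
    csv = {
      tab <- utils::read.csv(source, stringsAsFactors = FALSE)
      need <- c("splash_id", "compound_id", "compound_name", "neutral_mass",
                "polarity", "fragment_mz", "fragment_intensity")
      if (!all(need %in% names(tab)))
        stop("library CSV must have columns: ", paste(need, collapse = ", "))
      lapply(split(tab, factor(tab$splash_id, levels = unique(tab$splash_id))),
             function(g) {
        rec <- as.list(g[1, setdiff(names(g), c("fragment_mz", "fragment_intensity"))])
        rec$fragments <- data.frame(mz = g$fragment_mz,
                                    intensity = g$fragment_intensity)
        rec
      })
    },
    json = {
      objs <- jsonlite::fromJSON(source, simplifyVector = FALSE)
      lapply(objs, function(o) {
        frag <- do.call(rbind, lapply(o$fragments, function(f)
          data.frame(mz = f$mz, intensity = f$intensity)))
        o$fragments <- if (is.null(frag))
          data.frame(mz = numeric(0), intensity = numeric(0)) else frag
        o
      })
    }
  )
  keep <- vapply(recs, function(r) nrow(r$fragments) > 0L, logical(1))
  if (any(!keep))
    warning(sprintf("dropping %d record(s) with zero fragments (indices: %s)",
                    sum(!keep), paste(which(!keep), collapse = ", ")))
  recs <- recs[keep]
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) out[[i]] <- .record_to_spectrum(recs[[i]], i)
  unname(out)
}

#' Serialise library spectra
#'
#' Writers for the msp, csv and json dialects understood by
#' \code{\link{parse_spectra}}; parse(write(x)) reproduces the curated
#' content exactly.
#'
#' @param spectra list of \code{\link{library_spectrum}}.
#' @param path output file.
#' @param dialect "msp", "csv" or "json".
#' @return path, invisibly.
#' @export
write_spectra <- function(spectra, path, dialect = c("msp", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "msp") {
    lines <- unlist(lapply(spectra, function(s) c(
      paste0("NAME: ", s$compound_name),
      paste0("COMPOUND_ID: ", s$compound_id),
      paste0("SPLASH: ", s$splash_id),
      sprintf("EXACTMASS: %.6f", s$neutral_mass),
      paste0("IONMODE: ", s$polarity),
      paste0("RESOLUTION: ", s$resolution),
      if (!is.na(s$collision_energy))
        sprintf("COLLISIONENERGY: %g", s$collision_energy),
      sprintf("Num Peaks: %d", nrow(s$fragments)),
      sprintf("%.6f %.6g", s$fragments$mz, s$fragments$intensity),
      ""
    )))
    writeLines(lines, path)
  } else if (dialect == "csv") {
    tab <- do.call(rbind, lapply(spectra, function(s)
      data.frame(splash_id = s$splash_id, compound_id = s$compound_id,
                 compound_name = s$compound_name, neutral_mass = s$neutral_mass,
                 polarity = s$polarity, resolution = s$resolution,
                 collision_energy = s$collision_energy,
                 fragment_mz = s$fragments$mz,
                 fragment_intensity = s$fragments$intensity)))
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    objs <- lapply(spectra, function(s) {
      s <- unclass(s)
      s$fragments <- lapply(seq_len(nrow(s$fragments)), function(i)
        list(mz = s$fragments$mz[i], intensity = s$fragments$intensity[i]))
      s
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Relative fragment intensities
#'
#' Scales fragment intensities so the base peak is exactly 100; ties all
#' reach 100. Order is preserved.
#'
#' @param spectrum a \code{\link{library_spectrum}} (or a data.frame with mz
#'   and intensity columns).
#' @return data.frame with columns mz and relative_intensity.
#' @export
normalize_relative <- function(spectrum) {
  frag <- if (inherits(spectrum, "library_spectrum")) spectrum$fragments
          else as.data.frame(spectrum)
  if (nrow(frag) == 0L) stop("no fragments to normalise")
  m <- max(frag$intensity)
  if (m <= 0) stop("degenerate spectrum: all fragment intensities are zero")
  data.frame(mz = frag$mz, relative_intensity = 100 * frag$intensity / m)
}

#' Tag fragments as main/secondary daughters and drop noise-level ones
#'
#' Fragments below \code{rel_int_min} percent relative intensity are
#' excluded; survivors are tagged "D" (main daughter) strictly above
#' \code{d_threshold} percent, otherwise "F" (secondary daughter). Both
#' thresholds are strict inequalities, so exactly 5 is retained as F and
#' exactly 75 is F.
#'
#' @param fragments data.frame with mz and relative_intensity (0-100 scale).
#' @param rel_int_min exclusion threshold, percent (default 5).
#' @param d_threshold main-daughter threshold, percent (default 75).
#' @return data.frame with columns mz, relative_intensity, tag.
#' @export
tag_and_filter <- function(fragments, rel_int_min = 5, d_threshold = 75) {
  keep <- fragments$relative_intensity >= rel_int_min
  out <- fragments[keep, , drop = FALSE]
  out$tag <- ifelse(out$relative_intensity > d_threshold, "D", "F")
  rownames(out) <- NULL
  out
}

#' Collapse near-duplicate fragment m/z values
#'
#' Public repositories pool spectra from different instruments, so the same
#' transition can recur with a slight mass shift. Fragments whose m/z differ
#' by at most \code{mz_tol} are merged, keeping the entry with the highest
#' relative intensity (single-linkage on the sorted m/z ladder).
#'
#' @param fragments data.frame with mz, relative_intensity and optionally tag.
#' @param mz_tol merge tolerance in Da (default 0.01).
#' @return data.frame of distinct fragments, input-ordered by the kept rows.
#' @export
collapse_near_duplicates <- function(fragments, mz_tol = 0.01) {
  stopifnot(mz_tol > 0)
  n <- nrow(fragments)
  if (n <= 1L) return(fragments)
  ord <- order(fragments$mz)
  gaps <- diff(fragments$mz[ord])
  grp_sorted <- cumsum(c(1L, as.integer(gaps > mz_tol)))
  grp <- integer(n); grp[ord] <- grp_sorted
  keep <- vapply(split(seq_len(n), grp), function(idx)
    idx[which.max(fragments$relative_intensity[idx])], integer(1))
  out <- fragments[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One curated DIA transition record
#'
#' Runs the full curation chain on a raw library spectrum and attaches the
#' per-adduct precursor m/z values with their SWATH window indices. Spectra
#' left without a main daughter (tag D), or whose precursor m/z all fall
#' outside the acquisition range, are rejected (returned as NULL with a
#' "rejection" attribute-free message via \code{attr(,"reason")} on a
#' \code{dia_rejection} object).
#'
#' @param spectrum a \code{\link{library_spectrum}}.
#' @param adducts adduct table restricted to the spectrum's polarity
#'   (default: built-in table for that polarity).
#' @param scheme a \code{\link{swath_scheme}}.
#' @param rel_int_min,d_threshold,dedup_mz_tol curation thresholds, see
#'   \code{\link{tag_and_filter}} and \code{\link{collapse_near_duplicates}}.
#' @return object of class "dia_entry", or of class "dia_rejection" (with a
#'   \code{reason} field) when the spectrum cannot enter the database.
#' @export
build_dia_entry <- function(spectrum, adducts = NULL, scheme = swath_scheme(),
                            rel_int_min = 5, d_threshold = 75,
                            dedup_mz_tol = 0.01) {
  stopifnot(inherits(spectrum, "library_spectrum"))
  if (is.null(adducts)) adducts <- adduct_table(spectrum$polarity)
  if (!all(adducts$polarity == spectrum$polarity))
    stop("adduct table polarity does not match spectrum polarity")
  frag <- normalize_relative(spectrum)
  frag <- tag_and_filter(frag, rel_int_min, d_threshold)
  frag <- collapse_near_duplicates(frag, dedup_mz_tol)
  # fragments outside the acquisition range can never be observed
  frag <- frag[frag$mz >= scheme$start & frag$mz <= scheme$end, , drop = FALSE]
  reject <- function(reason) structure(
    list(compound_id = spectrum$compound_id, splash_id = spectrum$splash_id,
         reason = reason), class = "dia_rejection")
  if (nrow(frag) == 0L || !any(frag$tag == "D"))
    return(reject("no main daughter (D) fragment after curation"))
  mzs <- spectrum$neutral_mass + adducts$mass_delta
  in_range <- mzs >= scheme$start & mzs <= scheme$end
  if (!any(in_range))
    return(reject("all adduct precursor m/z outside acquisition range"))
  precursors <- data.frame(
    adduct = adducts$name[in_range], mz = mzs[in_range],
    window_index = assign_window(mzs[in_range], scheme),
    stringsAsFactors = FALSE)
  frag <- frag[order(-frag$relative_intensity, frag$mz), ]
  rownames(frag) <- NULL
  structure(
    list(compound_id = spectrum$compound_id, splash_id = spectrum$splash_id,
         compound_name = spectrum$compound_name,
         neutral_mass = spectrum$neutral_mass, polarity = spectrum$polarity,
         precursors = precursors, fragments = frag),
    class = "dia_entry"
  )
}

#' @export
print.dia_entry <- function(x, ...) {
  cat(sprintf("<dia_entry> %s (%s): %d precursor(s), %d fragment(s) [%d D]\n",
              x$compound_name, x$splash_id, nrow(x$precursors),
              nrow(x$fragments), sum(x$fragments$tag == "D")))
  invisible(x)
}

#' Curate a parsed library into the DIA transition database
#'
#' @param spectra list of \code{\link{library_spectrum}}.
#' @inheritParams build_dia_entry
#' @return list with \code{entries} (dia_entry list) and \code{rejections}
#'   (data.frame compound_id, splash_id, reason).
#' @export
curate_library <- function(spectra, scheme = swath_scheme(), rel_int_min = 5,
                           d_threshold = 75, dedup_mz_tol = 0.01) {
  res <- lapply(spectra, build_dia_entry, scheme = scheme,
                rel_int_min = rel_int_min, d_threshold = d_threshold,
                dedup_mz_tol = dedup_mz_tol)
  ok <- vapply(res, inherits, logical(1), "dia_entry")
  rejections <- if (any(!ok)) {
    do.call(rbind, lapply(res[!ok], function(r)
      data.frame(compound_id = r$compound_id, splash_id = r$splash_id,
                 reason = r$reason, stringsAsFactors = FALSE)))
  } else {
    data.frame(compound_id = character(0), splash_id = character(0),
               reason = character(0))
  }
  list(entries = res[ok], rejections = rejections)
}

#' Write / read the DIA transition database
#'
#' Long CSV with one row per (precursor adduct x fragment); JSON as an array
#' of entry objects. Both round-trip through \code{\link{read_dia_library}}.
#'
#' @param entries list of dia_entry objects.
#' @param path output file (.csv or .json decides the format unless
#'   \code{format} is given).
#' @param format "csv" or "json".
#' @return path, invisibly.
#' @export
write_dia_library <- function(entries, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    tab <- do.call(rbind, lapply(entries, function(e) {
      grid <- expand.grid(p = seq_len(nrow(e$precursors)),
                          f = seq_len(nrow(e$fragments)))
      data.frame(compound_id = e$compound_id, splash_id = e$splash_id,
                 compound_name = e$compound_name,
                 neutral_mass = e$neutral_mass, polarity = e$polarity,
                 adduct = e$precursors$adduct[grid$p],
                 precursor_mz = e$precursors$mz[grid$p],
                 window_index = e$precursors$window_index[grid$p],
                 fragment_mz = e$fragments$mz[grid$f],
                 relative_intensity = e$fragments$relative_intensity[grid$f],
                 tag = e$fragments$tag[grid$f], stringsAsFactors = FALSE)
    }))
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    objs <- lapply(entries, function(e) {
      list(compound_id = e$compound_id, splash_id = e$splash_id,
           compound_name = e$compound_name, neutral_mass = e$neutral_mass,
           polarity = e$polarity,
           precursors = lapply(seq_len(nrow(e$precursors)), function(i)
             as.list(e$precursors[i, ])),
           fragments = lapply(seq_len(nrow(e$fragments)), function(i)
             as.list(e$fragments[i, ])))
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dia_library
#' @export
read_dia_library <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(split(tab, factor(tab$splash_id, levels = unique(tab$splash_id))),
           function(g) {
      prec <- unique(g[, c("adduct", "precursor_mz", "window_index")])
      frag <- unique(g[, c("fragment_mz", "relative_intensity", "tag")])
      frag <- frag[order(-frag$relative_intensity, frag$fragment_mz), ]
      structure(
        list(compound_id = g$compound_id[1], splash_id = g$splash_id[1],
             compound_name = g$compound_name[1],
             neutral_mass = g$neutral_mass[1], polarity = g$polarity[1],
             precursors = data.frame(adduct = prec$adduct, mz = prec$precursor_mz,
                                     window_index = prec$window_index,
                                     stringsAsFactors = FALSE),
             fragments = data.frame(mz = frag$fragment_mz,
                                    relative_intensity = frag$relative_intensity,
                                    tag = frag$tag, stringsAsFactors = FALSE)),
        class = "dia_entry")
    }) |> unname()
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(objs, function(o) {
      prec <- do.call(rbind, lapply(o$precursors, as.data.frame))
      frag <- do.call(rbind, lapply(o$fragments, as.data.frame))
      structure(
        list(compound_id = o$compound_id, splash_id = o$splash_id,
             compound_name = o$compound_name, neutral_mass = o$neutral_mass,
             polarity = o$polarity, precursors = prec, fragments = frag),
        class = "dia_entry")
    })
  }
}
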