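# Peak-list handling and chemical shift perturbation (CSP) computation.
# Peak lists follow the Sparky text convention: one line per peak with an
# assignment label, the heavy-atom dimension (15N or 13C) as w1 and the 1H
# dimension as w2.

#' Default CSP significance thresholds (ppm)
#'
#' A residue is significantly perturbed when |delta-delta| strictly exceeds
#' 0.05 ppm in the amide-proton dimension or 0.20 ppm in the heavy-atom
#' dimension.
#' @export
CSP_THRESHOLDS <- c(H = 0.05, heavy = 0.20)

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited lines \code{label w1 w2}; lines starting with
#' \code{#} are comments, and a comment of the form \code{# nuclei: 1H-15N}
#' sets the nucleus-pair tag.  A Sparky \code{Assignment ...} header line is
#' skipped.
#'
#' @param path text file path.
#' @param nuclei nucleus-pair tag used when the file carries none
#'   (default \code{"1H-15N"}).
#' @return a \code{peak_list}: data frame with columns \code{label},
#'   \code{w1} (heavy), \code{w2} (1H) and a \code{nuclei} attribute.
#' @export
read_peaklist <- function(path, nuclei = "1H-15N") {
  lines <- readLines(path)
  tagline <- grep("^#\\s*nuclei:", lines, value = TRUE)
  if (length(tagline) > 0)
    nuclei <- trimws(sub("^#\\s*nuclei:", "", tagline[1]))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- lines[!grepl("^\\s*Assignment", lines)]
  if (length(lines) == 0) return(peak_list(character(0), numeric(0),
                                           numeric(0), nuclei))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed peak line(s): ",
                     paste(lines[bad], collapse = "; "))
  label <- vapply(parts, `[`, character(1), 1)
  w1 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  w2 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (anyNA(w1) || anyNA(w2))
    stop("non-numeric chemical shifts in ", path)
  peak_list(label, w1, w2, nuclei)
}

#' Construct a peak list in memory
#' @param label assignment labels (must be unique).
#' @param w1 heavy-atom (15N/13C) shifts in ppm.
#' @param w2 1H shifts in ppm.
#' @param nuclei nucleus-pair tag.
#' @return a \code{peak_list}.
#' @export
peak_list <- function(label, w1, w2, nuclei = "1H-15N") {
  if (anyDuplicated(label))
    stop("duplicate assignment labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  out <- data.frame(label = as.character(label), w1 = w1, w2 = w2,
                    stringsAsFactors = FALSE)
  attr(out, "nuclei") <- nuclei
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Write a peak list in Sparky-style text form
#' @param peaks a \code{peak_list}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# nuclei:", attr(peaks, "nuclei")), con)
  writeLines(sprintf("%-12s %9.3f %9.3f", peaks$label, peaks$w1, peaks$w2),
             con)
  invisible(path)
}

#' Chemical shift perturbations between two peak lists
#'
#' Peaks are matched by assignment label; \code{delta = complex - reference}
#' in each dimension.  A dimension is flagged significant when its absolute
#' perturbation strictly exceeds the threshold.
#'
#' @param reference peak list of the free protein.
#' @param complexed peak list in the presence of ligand.
#' @param thresholds named vector \code{c(H =, heavy =)} in ppm.
#' @return a data frame of class \code{delta_shifts} with columns
#'   \code{label}, \code{d_heavy}, \code{d_H}, \code{sig_heavy},
#'   \code{sig_H}; unmatched labels are reported in the
#'   \code{unmatched_reference} / \code{unmatched_complex} attributes.
#' @export
delta_shifts <- function(reference, complexed, thresholds = CSP_THRESHOLDS) {
  if (!identical(attr(reference, "nuclei"), attr(complexed, "nuclei")))
    stop("nucleus-pair mismatch: '", attr(reference, "nuclei"), "' vs '",
         attr(complexed, "nuclei"), "'")
  common <- intersect(reference$label, complexed$label)
  ir <- match(common, reference$label)
  ic <- match(common, complexed$label)
  out <- data.frame(label = common,
                    d_heavy = complexed$w1[ic] - reference$w1[ir],
                    d_H = complexed$w2[ic] - reference$w2[ir],
                    stringsAsFactors = FALSE)
  # strict inequality at the threshold, with a guard against floating-point
  # noise in the subtraction (a shift difference of exactly 0.05 ppm is NOT
  # significant at a 0.05 ppm threshold)
  eps <- 1e-9
  out$sig_heavy <- abs(out$d_heavy) > thresholds[["heavy"]] + eps
  out$sig_H <- abs(out$d_H) > thresholds[["H"]] + eps
  attr(out, "unmatched_reference") <- setdiff(reference$label, common)
  attr(out, "unmatched_complex") <- setdiff(complexed$label, common)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("delta_shifts", "data.frame")
  out
}
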