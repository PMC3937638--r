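# The eight-position HA-binding groove, binding-register enumeration, and
# register inference from NMR reporter classes.
#
# Groove positions are numbered 1-8 from the His45 end; odd positions hold
# uronic acids.  An oligomer bound at offset `o` places ring r at groove
# position o + r; rings at positions < 1 or > 8 overhang the groove ends.

#' Default groove model
#'
#' Positions 1-8 with their interaction features: 1 His45 stack + Lys63 salt
#' bridge; 2 Cys47/Cys68 van der Waals; 3 Lys11 salt bridge; 4 Ile61 methyl
#' pocket + Tyr12 hydrogen bond; 5 Tyr59 stack; 6 Tyr78 stack + hydrogen
#' bond + methyl pocket; 7 Arg81 salt bridge; 8 none.  The per-position
#' feature count is the interaction score contributed by an occupied
#' position.
#'
#' @param max_overhang largest number of rings allowed beyond either groove
#'   end.
#' @param min_in_groove smallest number of rings that must occupy groove
#'   positions.
#' @return an object of class \code{groove_model}.
#' @export
groove_model <- function(max_overhang = 2, min_in_groove = 4) {
  features <- data.frame(
    position = 1:8,
    n_features = c(2, 1, 1, 2, 1, 3, 1, 0),
    description = c("His45 stack + Lys63 salt bridge",
                    "Cys47-Cys68 van der Waals",
                    "Lys11 salt bridge",
                    "Ile61 methyl pocket + Tyr12 H-bond",
                    "Tyr59 stack",
                    "Tyr78 stack + H-bond + methyl pocket",
                    "Arg81 salt bridge",
                    "none"),
    stringsAsFactors = FALSE)
  structure(list(n_positions = 8, features = features,
                 max_overhang = max_overhang,
                 min_in_groove = min_in_groove),
            class = "groove_model")
}

#' @export
print.groove_model <- function(x, ...) {
  cat("<groove_model> positions 1-", x$n_positions,
      " (odd = GlcUA); overhang <= ", x$max_overhang,
      " per end, >= ", x$min_in_groove, " rings in groove\n", sep = "")
  for (i in seq_len(nrow(x$features)))
    cat(sprintf("  %d: %s\n", x$features$position[i],
                x$features$description[i]))
  invisible(x)
}

.register <- function(seq, offset, groove) {
  n <- length(seq$residues)
  positions <- offset + seq_len(n)
  ingroove <- positions[positions >= 1 & positions <= groove$n_positions]
  score <- sum(groove$features$n_features[groove$features$position %in%
                                            ingroove])
  structure(list(oligomer = seq$spec, offset = offset, positions = positions,
                 occupied = ingroove,
                 overhang_nonreducing = sum(positions < 1),
                 overhang_reducing = sum(positions > groove$n_positions),
                 reducing_position = positions[n], score = score),
            class = "register")
}

#' @export
print.register <- function(x, ...) {
  cat("<register> ", x$oligomer, " at positions ",
      min(x$positions), "-", max(x$positions),
      " (in-groove ", paste(range(x$occupied), collapse = "-"),
      ", score ", x$score, ")\n", sep = "")
  invisible(x)
}

#' Enumerate candidate binding registers of an oligomer
#'
#' All placements satisfying the parity rule (uronic acids on odd groove
#' positions for every in-groove ring), at most \code{max_overhang} rings
#' beyond each groove end, and at least \code{min_in_groove} rings inside
#' the groove.  Candidates are returned sorted by decreasing interaction
#' score.
#'
#' @param oligomer a \code{glycan_sequence} or specifier string.
#' @param groove a \code{groove_model}.
#' @return list of \code{register} objects (possibly empty).
#' @export
enumerate_registers <- function(oligomer, groove = groove_model()) {
  if (is.character(oligomer)) oligomer <- parse_glycan(oligomer)
  n <- length(oligomer$residues)
  uronic <- vapply(oligomer$residues, is_uronic, logical(1))
  out <- list()
  for (offset in seq(-groove$max_overhang,
                     groove$n_positions + groove$max_overhang - n)) {
    positions <- offset + seq_len(n)
    inside <- positions >= 1 & positions <= groove$n_positions
    if (sum(inside) < groove$min_in_groove) next
    if (sum(positions < 1) > groove$max_overhang) next
    if (sum(positions > groove$n_positions) > groove$max_overhang) next
    if (!all((positions[inside] %% 2 == 1) == uronic[inside])) next
    out[[length(out) + 1]] <- .register(oligomer, offset, groove)
  }
  out[order(-vapply(out, function(r) r$score, numeric(1)))]
}

#' Reporter rule table
#'
#' Maps each NMR reporter residue to its peak-class predicate on groove
#' occupancy: Val62 reports whether position 1 is occupied (class II) or
#' not (I); Lys63 distinguishes position 1 occupied (III), position 1 empty
#' but 2 occupied (IV), and both empty (V); His45 mirrors Lys63 with
#' classes VI/VII/VIII; Ala49 (with Tyr78) reports a GlcUA at position 7
#' (IX) versus a reducing terminus at position 6 (X), and is otherwise
#' unclassified.  Registers predicted "unclassified" for a reporter impose
#' no constraint during inference.
#'
#' @param include_his45 include the optional His45 mirror reporter.
#' @return named list of predicate functions
#'   \code{function(occupied, reducing_position) -> label}.
#' @export
reporter_rules <- function(include_his45 = FALSE) {
  rules <- list(
    Val62 = function(occ, red) if (1 %in% occ) "II" else "I",
    Lys63 = function(occ, red) {
      if (1 %in% occ) "III" else if (2 %in% occ) "IV" else "V"
    },
    Ala49 = function(occ, red) {
      if (7 %in% occ) "IX" else if (red == 6) "X" else "unclassified"
    })
  if (include_his45)
    rules$His45 <- function(occ, red) {
      if (1 %in% occ) "VI" else if (2 %in% occ) "VII" else "VIII"
    }
  rules
}

#' Predict reporter peak classes for a register
#'
#' @param register a \code{register}.
#' @param rules a \code{\link{reporter_rules}} list.
#' @return named character vector of class labels, one per reporter.
#' @export
predict_classes <- function(register, rules = reporter_rules()) {
  vapply(rules, function(rule)
    rule(register$occupied, register$reducing_position), character(1))
}

#' Infer binding registers from observed reporter classes
#'
#' Keeps the enumerated candidates whose predicted class for every observed
#' reporter lies within the observed set (an "unclassified" prediction
#' imposes no constraint), then selects the smallest candidate subset whose
#' predictions jointly cover every observed class, breaking ties by higher
#' total interaction score.  Multiple selected registers are reported as
#' coexisting binding modes.
#'
#' @param oligomer sequence or specifier.
#' @param observed named list, reporter -> character vector of observed
#'   class labels (at least one reporter).
#' @param groove a \code{groove_model}.
#' @param rules reporter rules.
#' @return list of class \code{register_inference}: \code{selected} (list
#'   of registers, each annotated with its predicted classes),
#'   \code{consistent} (all consistent candidates), \code{covered}
#'   (logical: did the selection cover every observed class) and
#'   \code{diagnostics} (per rejected candidate, the first violated
#'   reporter).
#' @export
infer_registers <- function(oligomer, observed, groove = groove_model(),
                            rules = reporter_rules()) {
  if (length(observed) == 0 || all(lengths(observed) == 0))
    stop("observed classes must be nonempty for at least one reporter")
  observed <- observed[lengths(observed) > 0]
  missing_rules <- setdiff(names(observed), names(rules))
  if (length(missing_rules) > 0)
    stop("no rule for reporter(s): ", paste(missing_rules, collapse = ", "))
  candidates <- enumerate_registers(oligomer, groove)
  consistent <- list()
  diagnostics <- character(0)
  for (cand in candidates) {
    pred <- predict_classes(cand, rules[names(observed)])
    bad <- names(pred)[pred != "unclassified" &
                         !mapply(function(p, o) p %in% o, pred,
                                 observed[names(pred)])]
    if (length(bad) > 0) {
      diagnostics <- c(diagnostics,
                       sprintf("offset %+d: %s predicts %s, observed {%s}",
                               cand$offset, bad[1], pred[bad[1]],
                               paste(observed[[bad[1]]], collapse = ",")))
    } else {
      cand$predicted <- pred
      consistent[[length(consistent) + 1]] <- cand
    }
  }
  if (length(consistent) == 0)
    return(structure(list(selected = list(), consistent = list(),
                          covered = FALSE, diagnostics = diagnostics),
                     class = "register_inference"))
  # minimal subset covering all observed classes; ties -> higher score
  target <- unlist(lapply(names(observed), function(r)
    paste0(r, ":", observed[[r]])))
  covers <- lapply(consistent, function(cand)
    paste0(names(cand$predicted), ":", cand$predicted))
  best <- NULL
  nmax <- length(consistent)
  for (size in seq_len(nmax)) {
    for (idx in utils::combn(nmax, size, simplify = FALSE)) {
      covered <- sum(target %in% unlist(covers[idx]))
      score <- sum(vapply(consistent[idx], function(r) r$score, numeric(1)))
      if (is.null(best) || covered > best$covered ||
          (covered == best$covered && size < best$size) ||
          (covered == best$covered && size == best$size &&
             score > best$score))
        best <- list(idx = idx, size = size, score = score,
                     covered = covered)
    }
    # sizes ascend, so the first size achieving full coverage is minimal
    if (best$covered == length(target)) break
  }
  selected <- consistent[best$idx]
  structure(list(selected = selected, consistent = consistent,
                 covered = best$covered == length(target),
                 diagnostics = diagnostics),
            class = "register_inference")
}

#' @export
print.register_inference <- function(x, ...) {
  cat("<register_inference> ", length(x$selected), " register(s) selected",
      if (!x$covered) " (observed classes NOT fully covered)", "\n",
      sep = "")
  for (r in x$selected) {
    cat(sprintf("  offset %+d, positions %d-%d, score %d: %s\n",
                r$offset, min(r$positions), max(r$positions), r$score,
                paste(names(r$predicted), r$predicted, sep = "=",
                      collapse = " ")))
  }
  if (length(x$selected) == 0 && length(x$diagnostics) > 0)
    cat(paste("  ", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

#' Shortest oligomer that fills the groove
#'
#' Over a family of oligomers, finds the minimal ring count for which some
#' member has an enumerated register occupying every position in
#' \code{cover} (default 1-7, the positions with interaction features).
#'
#' @param groove a \code{groove_model}.
#' @param lengths ring counts to consider.
#' @param cover set of groove positions to be occupied simultaneously.
#' @return list with \code{length} (minimal ring count, NA if none works)
#'   and \code{witnesses} (specifier strings).
#' @export
full_fill_length <- function(groove = groove_model(), lengths = 4:8,
                             cover = 1:7) {
  family <- unlist(lapply(sort(lengths), function(n) {
    terms <- if (n %% 2 == 0) c("AN", "NA") else c("AA", "NN")
    paste0("HA", n, "^", terms)
  }))
  for (n in sort(unique(lengths))) {
    members <- family[as.integer(sub("^HA([0-9]+).*", "\\1", family)) == n]
    witnesses <- character(0)
    for (spec in members) {
      regs <- enumerate_registers(spec, groove)
      if (any(vapply(regs, function(r) all(cover %in% r$occupied),
                     logical(1))))
        witnesses <- c(witnesses, spec)
    }
    if (length(witnesses) > 0)
      return(list(length = n, witnesses = witnesses))
  }
  list(length = NA_integer_, witnesses = character(0))
}

#' Read an observed-class YAML file
#'
#' Maps reporter names to lists of observed class labels.
#' @param path YAML file.
#' @return named list of character vectors.
#' @export
read_observed_classes <- function(path) {
  lapply(yaml::read_yaml(path), function(x) as.character(unlist(x)))
}

#' Write selected registers as a TSV report
#' @param inference a \code{register_inference}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_registers_tsv <- function(inference, path) {
  rows <- lapply(inference$selected, function(r)
    data.frame(oligomer = r$oligomer, offset = r$offset,
               positions = paste(range(r$positions), collapse = "-"),
               occupied = paste(r$occupied, collapse = ","),
               score = r$score,
               classes = paste(names(r$predicted), r$predicted, sep = "=",
                               collapse = ";"),
               stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(oligomer = character(0), offset = integer(0),
               positions = character(0), occupied = character(0),
               score = integer(0), classes = character(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
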