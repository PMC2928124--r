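# Hydrophobic-core edge refinement and cytosolic-edge alignment.
#
# A TMD's approximate (guide) interval is refined into hydrophobic-core
# edges by a sliding-window scan: starting 4 residues inside the guide edge,
# a 5-residue window centred on the candidate position moves outward one
# residue at a time, and the edge is the outermost candidate whose window
# mean stays at or below the scale's window threshold and whose own value
# stays at or below the individual-residue threshold (on the GES scale the
# residue rule excludes D, E, K and R). Windows are truncated at sequence
# termini and the scan stops at the sequence end.

scan_seq_side <- function(values, guide_lo, guide_hi, seq_side, scale,
                          overshoot = 4L) {
  n <- length(values)
  w_half <- (scale$window - 1L) %/% 2L
  if (seq_side == "N") {
    start <- guide_lo + scale$indent
    candidates <- seq(min(start, n), max(1L, guide_lo - overshoot))
  } else {
    start <- guide_hi - scale$indent
    candidates <- seq(max(start, 1L), min(n, guide_hi + overshoot))
  }
  best <- NA_integer_
  for (c_pos in candidates) {
    win <- values[max(1L, c_pos - w_half):min(n, c_pos + w_half)]
    if (mean(win) <= scale$window_threshold &&
        values[c_pos] <= scale$residue_threshold) {
      best <- c_pos
    }
  }
  if (is.na(best)) abort("no hydrophobic core")
  best
}

#' Scan one edge of a hydrophobic core
#'
#' Low-level single-edge scan. `side` names the membrane side of the edge;
#' for a type II protein the cytosolic edge lies on the N-terminal side of
#' the guide interval, for types I and III on the C-terminal side.
#'
#' @param sequence Amino-acid string.
#' @param guide_start,guide_end Guide TMD interval, 1-based inclusive.
#' @param side `"cytosolic"` or `"exoplasmic"`.
#' @param scale A [hydrophobicity_scale()].
#' @param topology `"I"`, `"II"` or `"III"` (default `"II"`).
#' @param overshoot How far past the guide edge the scan may continue
#'   (residues, default 4); guide edges are approximate, but an unbounded
#'   scan could latch onto mildly hydrophobic patches far from the
#'   membrane. The scan is always clamped at the sequence ends.
#' @return 1-based sequence index of the refined edge.
#' @export
scan_edge <- function(sequence, guide_start, guide_end,
                      side = c("cytosolic", "exoplasmic"),
                      scale = hydrophobicity_scale("ges"),
                      topology = "II", overshoot = 4L) {
  side <- match.arg(side)
  if (guide_end - guide_start + 1L < scale$indent + scale$window) {
    abort("guide interval shorter than indent + window")
  }
  values <- scale$values[strsplit(sequence, "")[[1]]]
  if (anyNA(values)) abort("sequence contains residues absent from the scale")
  cyt_is_n <- topology == "II"
  seq_side <- if ((side == "cytosolic") == cyt_is_n) "N" else "C"
  scan_seq_side(unname(values), guide_start, guide_end, seq_side, scale,
                overshoot = as.integer(overshoot))
}

#' Annotate hydrophobic-core edges of protein TMDs
#'
#' Refines every guide interval into cytosolic and exoplasmic edges with
#' [scan_edge()] and records the hydrophobic length (residues between the
#' two edges, inclusive). Edges are reported as sequence indices; for types
#' I and III the cytosolic edge is the C-terminal one, so
#' `cytosolic_edge > exoplasmic_edge` for those topologies.
#'
#' @param proteins Protein tibble.
#' @param scale A [hydrophobicity_scale()].
#' @param on_error `"error"` (default) to propagate scan failures, `"drop"`
#'   to discard failing proteins with a warning naming them.
#' @param overshoot Scan bound past the guide edge; see [scan_edge()].
#' @return A tibble of class `tmd_annotation` with columns `id`, `topology`,
#'   `organelle`, `cytosolic_edge`, `exoplasmic_edge`, `hydrophobic_length`,
#'   `scale`.
#' @export
annotate_tmds <- function(proteins, scale = hydrophobicity_scale("ges"),
                          on_error = c("error", "drop"), overshoot = 4L) {
  on_error <- match.arg(on_error)
  rows <- purrr::pmap(proteins, function(id, sequence, topology,
                                         tmd_start, tmd_end, ...) {
    dots <- list(...)
    res <- tryCatch({
      cyt <- scan_edge(sequence, tmd_start, tmd_end, side = "cytosolic",
                       scale = scale, topology = topology, overshoot = overshoot)
      exo <- scan_edge(sequence, tmd_start, tmd_end, side = "exoplasmic",
                       scale = scale, topology = topology, overshoot = overshoot)
      if ((topology == "II" && cyt > exo) || (topology != "II" && cyt < exo)) {
        abort("edges crossed: no hydrophobic core")
      }
      tibble(id = id, topology = topology,
             organelle = dots$organelle %||% NA_character_,
             cytosolic_edge = cyt, exoplasmic_edge = exo,
             hydrophobic_length = abs(exo - cyt) + 1L,
             scale = scale$name)
    }, error = function(e) structure(conditionMessage(e), class = "scan_fail"))
    res
  })
  failed <- vapply(rows, inherits, logical(1), "scan_fail")
  if (any(failed)) {
    msgs <- paste0(proteins$id[failed], ": ", unlist(rows[failed]))
    if (on_error == "error") {
      abort(paste0("TMD annotation failed:\n  ", paste(msgs, collapse = "\n  ")))
    }
    warn(paste0("dropped ", sum(failed), " protein(s) with no detectable core:\n  ",
                paste(msgs, collapse = "\n  ")))
  }
  out <- bind_rows(rows[!failed])
  class(out) <- c("tmd_annotation", class(out))
  out
}

#' Annotate a single protein
#'
#' Convenience wrapper around [annotate_tmds()] for one protein.
#'
#' @inheritParams annotate_tmds
#' @param protein One-row protein tibble.
#' @return One-row `tmd_annotation` tibble.
#' @export
annotate_tmd <- function(protein, scale = hydrophobicity_scale("ges")) {
  annotate_tmds(protein[1, , drop = FALSE], scale = scale, on_error = "error")
}

#' Align TMDs from their cytosolic edge
#'
#' Re-indexes every protein so that position 1 is the cytosolic-edge residue
#' of the hydrophobic core and increasing positions run toward the
#' exoplasmic side: type II proteins are read N-to-C, types I and III
#' C-to-N. Positions 0, -1, ... are the cytosolic flank; positions beyond
#' the hydrophobic length are the exoplasmic flank/lumen. Flank positions
#' are included where sequence exists and absent otherwise.
#'
#' @param proteins Protein tibble.
#' @param annotations Edge annotations from [annotate_tmds()].
#' @param flank Number of flanking residues kept on each side.
#' @return A long tibble of class `tmd_aligned` with columns `id`,
#'   `organelle`, `topology`, `position`, `residue`; the annotations are
#'   attached as attribute `annotations`.
#' @export
align_tmds <- function(proteins, annotations, flank = 10) {
  ann <- annotations[match(proteins$id, annotations$id), ]
  keep <- !is.na(ann$id)
  if (!all(keep)) {
    warn(sprintf("align_tmds: %d protein(s) without annotation dropped", sum(!keep)))
    proteins <- proteins[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    s <- strsplit(proteins$sequence[i], "")[[1]]
    cyt <- ann$cytosolic_edge[i]
    len <- ann$hydrophobic_length[i]
    dir <- if (proteins$topology[i] == "II") 1L else -1L
    pos <- seq(1L - as.integer(flank), len + as.integer(flank))
    idx <- cyt + dir * (pos - 1L)
    ok <- idx >= 1L & idx <= length(s)
    tibble(id = proteins$id[i],
           organelle = proteins$organelle[i],
           topology = proteins$topology[i],
           position = pos[ok], residue = s[idx[ok]])
  })
  out <- bind_rows(rows)
  attr(out, "annotations") <- ann
  class(out) <- c("tmd_aligned", class(out))
  out
}

#' @rdname align_tmds
#' @param protein,annotation Single protein and its annotation row.
#' @export
orient_cytosolic <- function(protein, annotation, flank = 10) {
  align_tmds(protein[1, , drop = FALSE], annotation, flank = flank)
}

# residues of the aligned core (positions 1..L) as one string per protein
aligned_core_strings <- function(aligned) {
  ann <- attr(aligned, "annotations")
  aligned %>%
    left_join(select(ann, "id", "hydrophobic_length"), by = "id") %>%
    filter(.data$position >= 1, .data$position <= .data$hydrophobic_length) %>%
    arrange(.data$id, .data$position) %>%
    group_by(.data$id) %>%
    summarise(core = paste(.data$residue, collapse = ""), .groups = "drop")
}
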