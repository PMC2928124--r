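# End-to-end wrappers: proteins -> edges -> alignment -> encoding ->
# classifier.

#' Encode proteins for the classifier
#'
#' Runs edge annotation, cytosolic-edge alignment and region encoding in
#' one step.
#'
#' @param proteins Protein tibble.
#' @param scale A [hydrophobicity_scale()].
#' @param flank Flank residues carried into the alignment (>= 4 so the
#'   cytosolic region reaching position -3 is populated).
#' @return List with `encodings` (tibble from [encode_regions()]), `labels`
#'   (organelle per row), `annotations` and `aligned`.
#' @export
encode_proteins <- function(proteins, scale = hydrophobicity_scale("ges"),
                            flank = 10) {
  ann <- annotate_tmds(proteins, scale = scale)
  al <- align_tmds(proteins, ann, flank = flank)
  enc <- encode_regions(al)
  list(encodings = enc,
       labels = proteins$organelle[match(enc$id, proteins$id)],
       annotations = ann, aligned = al)
}

#' Cross-validate the organelle classifier on a protein set
#'
#' Convenience wrapper: equalizes class sizes, encodes every protein
#' ([encode_proteins()]) and runs seeded stratified [cross_validate()].
#'
#' @inheritParams cross_validate
#' @inheritParams encode_proteins
#' @param equalize Downsample classes to equal size first (default TRUE).
#' @return A `tmd_cv` object.
#' @export
crossval_organelles <- function(proteins, scale = hydrophobicity_scale("ges"),
                                k = 5, hidden = 7, rate = 0.01, epochs = 100,
                                seed = NULL, flank = 10, equalize = TRUE) {
  if (equalize) proteins <- equalize_sets(proteins, seed = seed)
  enc <- encode_proteins(proteins, scale = scale, flank = flank)
  cross_validate(enc$encodings, enc$labels, k = k, hidden = hidden,
                 rate = rate, epochs = epochs, seed = seed)
}

# mirror presentation: reverse each sequence (mapping the guide interval)
# while keeping the declared topology, so the network sees the TMD with its
# cytosolic and exoplasmic halves exchanged
reverse_proteins <- function(proteins) {
  n <- nchar(proteins$sequence)
  proteins %>%
    mutate(sequence = vapply(strsplit(.data$sequence, ""), function(s)
             paste(rev(s), collapse = ""), character(1)),
           tmd_start_new = n - .data$tmd_end + 1L,
           tmd_end = n - .data$tmd_start + 1L,
           tmd_start = .data$tmd_start_new) %>%
    select(-"tmd_start_new")
}

#' Predict organelle of residence for proteins
#'
#' Annotates, aligns and encodes the given proteins and scores them with a
#' trained network. With `reverse = TRUE` each residue string is reversed
#' (guide interval re-mapped) before re-annotation and encoding while the
#' declared topology is retained, presenting every TMD mirror-imaged --
#' the orientation-dependence probe: a topology-aware signal should degrade,
#' and a TMD that is mirror-symmetric about its core midpoint scores
#' identically either way.
#'
#' @param model A `tmd_ann` from [ann_train()].
#' @param proteins Protein tibble.
#' @param scale A [hydrophobicity_scale()].
#' @param reverse Present the sequences reversed (default FALSE).
#' @param flank Alignment flank (default 10).
#' @return Tibble with `id`, per-class scores and `.pred`.
#' @export
predict_organelle <- function(model, proteins,
                              scale = hydrophobicity_scale("ges"),
                              reverse = FALSE, flank = 10) {
  if (reverse) proteins <- reverse_proteins(proteins)
  enc <- encode_proteins(proteins, scale = scale, flank = flank)
  predict(model, enc$encodings)
}
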