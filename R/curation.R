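# Curation: ortholog-style quality filters, identity-based redundancy
# reduction over the TMD region, and class-size equalization.

identity_submat <- function() {
  m <- diag(1, length(AA_ALPHABET))
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

# global (Needleman-Wunsch) identities of each string in `a` against `b`:
# match +1, mismatch 0, linear gap penalty -1, identity = matches / columns
nw_identity_vec <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(a),
    subject = Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = identity_submat(),
    gapOpening = 0, gapExtension = 1
  )
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  purrr::map2_dbl(pa, sa, function(x, y) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    sum(cx == cy & cx != "-") / length(cx)
  })
}

#' Pairwise sequence identity under global alignment
#'
#' Fraction of identical alignment columns under a global Needleman-Wunsch
#' alignment with match = 1, mismatch = 0 and a linear gap penalty of -1;
#' identity = matches / alignment length (gap columns included in the
#' denominator). Symmetric in its arguments.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return A fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("LLLLL", "LLLLL")  # 1
#' pairwise_identity("LLLLL", "KKKKK")  # 0
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("pairwise_identity: empty sequence")
  nw_identity_vec(a, b)
}

# region used for identity clustering: hydrophobic core (annotation if
# given, else the guide interval) plus `flank` residues on either side
region_strings <- function(proteins, annotations = NULL, flank = 10) {
  if (!is.null(annotations)) {
    ann <- annotations[match(proteins$id, annotations$id), ]
    lo <- pmin(ann$cytosolic_edge, ann$exoplasmic_edge)
    hi <- pmax(ann$cytosolic_edge, ann$exoplasmic_edge)
  } else {
    lo <- proteins$tmd_start
    hi <- proteins$tmd_end
  }
  lo <- pmax(1L, lo - as.integer(flank))
  hi <- pmin(nchar(proteins$sequence), hi + as.integer(flank))
  substr(proteins$sequence, lo, hi)
}

# all-vs-all identity matrix for a character vector of regions
identity_matrix <- function(regions) {
  n <- length(regions)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      m[i, (i + 1):n] <- m[(i + 1):n, i] <- nw_identity_vec(regions[(i + 1):n], regions[i])
    }
  }
  m
}

# minimal union-find for single-linkage components
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Reduce redundancy within organelle datasets
#'
#' Single-linkage clusters proteins whose pairwise identity over the TMD
#' region (hydrophobic core plus `flank` residues each side) exceeds
#' `identity_threshold`, then keeps one representative per cluster, chosen
#' uniformly at random (seeded). Because linkage is single, every retained
#' pair is guaranteed to have identity at or below the threshold over that
#' region. Clustering is performed within each organelle label separately.
#'
#' @param proteins Protein tibble.
#' @param identity_threshold Linkage threshold, default 0.30.
#' @param flank Flanking residues included on each side of the core.
#' @param seed Integer seed for the random representative choice.
#' @param annotations Optional edge annotations from [annotate_tmds()]; when
#'   absent the guide interval stands in for the core.
#' @return The retained subset of `proteins`, with a `cluster` attribute
#'   giving the cluster index of every input protein.
#' @export
reduce_redundancy <- function(proteins, identity_threshold = 0.30, flank = 10,
                              seed = NULL, annotations = NULL) {
  if (nrow(proteins) == 0) return(proteins)
  pick <- function(df) {
    regions <- region_strings(df, annotations, flank)
    m <- identity_matrix(regions)
    edges <- which(m > identity_threshold & upper.tri(m), arr.ind = TRUE)
    comp <- uf_components(nrow(df), edges)
    reps <- vapply(split(seq_len(nrow(df)), comp), function(idx) {
      if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    }, integer(1))
    list(keep = df[sort(reps), , drop = FALSE],
         cluster = tibble(id = df$id, cluster = comp))
  }
  run <- function() {
    parts <- lapply(split_by_organelle(proteins), pick)
    out <- bind_rows(lapply(parts, `[[`, "keep"))
    attr(out, "clusters") <- bind_rows(lapply(parts, `[[`, "cluster"))
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Ortholog-style candidate filters
#'
#' Retains candidates that (i) are within +/-100 residues of the reference
#' protein's total length, (ii) contain, inside their guide TMD interval, at
#' least one 10-residue window whose mean hydropathy is at or below
#' -0.95 kcal/mol (hydrophobic negative), and (iii) are not exact sequence
#' duplicates of an earlier candidate. Candidates whose guide interval is
#' shorter than the hydrophobicity window are rejected.
#'
#' @param candidates Protein tibble.
#' @param reference A one-row protein tibble (or list with `sequence`).
#' @param scale A [hydrophobicity_scale()]; default GES.
#' @param length_tolerance Allowed absolute deviation in total length.
#' @param hydro_threshold Required best-window mean hydropathy (kcal/mol).
#' @param hydro_window Window size for the hydrophobicity filter.
#' @return The retained subset, with attribute `rejections`: a tibble of
#'   `id`, `reason` for every discarded candidate.
#' @export
filter_candidates <- function(candidates, reference,
                              scale = hydrophobicity_scale("ges"),
                              length_tolerance = 100,
                              hydro_threshold = -0.95,
                              hydro_window = 10) {
  ref_len <- nchar(reference$sequence[[1]])
  vals <- scale$values
  reasons <- character(nrow(candidates))
  seen <- character(0)
  for (i in seq_len(nrow(candidates))) {
    p <- candidates[i, ]
    if (abs(nchar(p$sequence) - ref_len) > length_tolerance) {
      reasons[i] <- sprintf("length deviates from reference by more than %d residues",
                            length_tolerance)
      next
    }
    lo <- p$tmd_start; hi <- p$tmd_end
    if (hi - lo + 1 < hydro_window) {
      reasons[i] <- "guide interval shorter than the hydrophobicity window"
      next
    }
    v <- vals[strsplit(substr(p$sequence, lo, hi), "")[[1]]]
    best <- min(stats::filter(v, rep(1 / hydro_window, hydro_window), sides = 1),
                na.rm = TRUE)
    if (best > hydro_threshold) {
      reasons[i] <- sprintf("best %d-residue TMD window mean %.2f kcal/mol above %.2f",
                            hydro_window, best, hydro_threshold)
      next
    }
    if (p$sequence %in% seen) {
      reasons[i] <- "exact duplicate of an earlier candidate"
      next
    }
    seen <- c(seen, p$sequence)
  }
  keep <- !nzchar(reasons)
  rejections <- tibble(id = candidates$id[!keep], reason = reasons[!keep])
  if (nrow(rejections) > 0) {
    inform(sprintf("filter_candidates: rejected %d of %d candidate(s)",
                   nrow(rejections), nrow(candidates)))
  }
  out <- candidates[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' Equalize organelle set sizes
#'
#' Removes proteins uniformly at random (seeded) from all but the smallest
#' organelle set so that every set has the same size, as required before
#' training the classifier.
#'
#' @param proteins Protein tibble with an `organelle` column.
#' @param seed Integer seed.
#' @return Tibble with equally many proteins per organelle.
#' @export
equalize_sets <- function(proteins, seed = NULL) {
  sizes <- table(proteins$organelle)
  if (length(sizes) == 0 || any(sizes == 0)) abort("equalize_sets: empty dataset")
  n_min <- min(sizes)
  run <- function() {
    proteins %>%
      group_by(.data$organelle) %>%
      slice(sort(sample.int(n(), n_min))) %>%
      ungroup()
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
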