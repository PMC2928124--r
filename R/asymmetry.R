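# Leaflet-preference ratios, the helical size moment, and consensus TMDs.

#' Leaflet-preference ratios
#'
#' For each protein the hydrophobic core is split at its midpoint: the inner
#' leaflet is positions `1..floor(L/2)` (cytosolic half) and the outer
#' leaflet the remainder, so with odd lengths the midpoint residue goes to
#' the outer half. Residue abundances are normalized within each leaflet and
#' each residue's preference is `(outer - inner) / (outer + inner)`: +1 for
#' a residue found only in the outer half, -1 only inner, 0 for no
#' preference. Per-residue ratios are computed per protein and then averaged
#' over the proteins in which the residue occurs at all, with the standard
#' error of that mean.
#'
#' @param aligned A `tmd_aligned` tibble.
#' @param annotations Matching `tmd_annotation` tibble; defaults to the
#'   annotations attached to `aligned`.
#' @return A tibble of class `tmd_leaflet` with columns `residue`, `ratio`,
#'   `sem`, `n_proteins`; residues absent from every protein's core are
#'   reported with `NA` ratio.
#' @export
leaflet_preference <- function(aligned, annotations = attr(aligned, "annotations")) {
  if (is.null(annotations)) abort("leaflet_preference: annotations required")
  core <- aligned %>%
    left_join(select(annotations, "id", "hydrophobic_length"), by = "id") %>%
    filter(.data$position >= 1, .data$position <= .data$hydrophobic_length)
  if (nrow(core) == 0) abort("leaflet_preference: no core residues")
  if (any(core$hydrophobic_length < 2)) abort("hydrophobic length < 2")
  per_protein <- core %>%
    mutate(leaflet = ifelse(.data$position <= floor(.data$hydrophobic_length / 2),
                            "inner", "outer")) %>%
    count(.data$id, .data$leaflet, .data$residue, name = "k") %>%
    group_by(.data$id, .data$leaflet) %>%
    mutate(abund = .data$k / sum(.data$k)) %>%
    ungroup() %>%
    select("id", "leaflet", "residue", "abund") %>%
    tidyr::pivot_wider(names_from = "leaflet", values_from = "abund",
                       values_fill = 0)
  for (col in c("inner", "outer")) {
    if (!col %in% names(per_protein)) per_protein[[col]] <- 0
  }
  per_protein <- per_protein %>%
    mutate(ratio = (.data$outer - .data$inner) / (.data$outer + .data$inner))
  out <- per_protein %>%
    group_by(.data$residue) %>%
    summarise(ratio_mean = mean(.data$ratio),
              sem = if (n() > 1) stats::sd(.data$ratio) / sqrt(n()) else 0,
              n_proteins = n(), .groups = "drop") %>%
    rename(ratio = "ratio_mean") %>%
    tidyr::complete(residue = AA_ALPHABET,
                    fill = list(ratio = NA_real_, sem = NA_real_, n_proteins = 0L)) %>%
    arrange(.data$residue)
  class(out) <- c("tmd_leaflet", class(out))
  out
}

# planar unit vectors at 100-degree increments
helix_angles <- function(k, step_deg = 100) {
  th <- (seq_len(k) - 1) * step_deg * pi / 180
  cbind(cos(th), sin(th))
}

#' Helical size moment along a sequence
#'
#' Treats each residue as a planar vector whose length is its volume and
#' whose angle advances by 100 degrees per residue (the twist of an ideal
#' alpha helix), sums the vectors over a 7-residue window (700 degrees,
#' almost two turns) and reports the magnitude of the sum at the window's
#' central residue. A flattened helix face -- small residues aligned on one
#' side, as in a GXXXG dimerization motif -- produces a local peak. The
#' angular origin only rotates the summed vector, so the reported magnitude
#' is origin-independent.
#'
#' @param residues An amino-acid string, or a `tmd_aligned` tibble holding a
#'   single protein (its residues are taken in positional order).
#' @param volumes Named per-residue volume table; default [residue_volumes()].
#' @param window Window size in residues (default 7).
#' @return A tibble of class `tmd_sizemoment` with columns `position` (index
#'   of the central residue, aligned coordinates when the input is aligned)
#'   and `moment` (cubic Angstrom). Positions whose window would extend past
#'   the available residues are skipped.
#' @export
size_moment <- function(residues, volumes = residue_volumes(), window = 7) {
  if (inherits(residues, "tmd_aligned") || is.data.frame(residues)) {
    if (length(unique(residues$id)) != 1) {
      abort("size_moment: supply a single protein (see size_moment_profile)")
    }
    residues <- arrange(residues, .data$position)
    pos <- residues$position
    chars <- residues$residue
  } else {
    chars <- strsplit(residues, "")[[1]]
    pos <- seq_along(chars)
  }
  n <- length(chars)
  if (n < window) {
    return(structure(tibble(position = integer(), moment = numeric()),
                     class = c("tmd_sizemoment", class(tibble()))))
  }
  v <- unname(volumes[chars])
  if (anyNA(v)) abort("size_moment: residue absent from volume table")
  half <- (window - 1) %/% 2
  centers <- (1 + half):(n - half)
  u <- helix_angles(window)
  moment <- vapply(centers, function(c_i) {
    w <- v[(c_i - half):(c_i + half)]
    sqrt(sum(w * u[, 1])^2 + sum(w * u[, 2])^2)
  }, numeric(1))
  structure(tibble(position = pos[centers], moment = moment),
            class = c("tmd_sizemoment", class(tibble())))
}

#' Mean size-moment profile over an aligned set
#'
#' Computes [size_moment()] for every protein in an aligned set and averages
#' the magnitudes at each aligned position.
#'
#' @param aligned A `tmd_aligned` tibble.
#' @param volumes,window As in [size_moment()].
#' @param min_n Positions with fewer contributing proteins are dropped.
#' @return Tibble with `position`, `mean`, `sem`, `n`.
#' @export
size_moment_profile <- function(aligned, volumes = residue_volumes(),
                                window = 7, min_n = 10) {
  per <- aligned %>%
    group_by(.data$id) %>%
    group_split() %>%
    purrr::map(size_moment, volumes = volumes, window = window) %>%
    bind_rows()
  per %>%
    group_by(.data$position) %>%
    summarise(mean = mean(.data$moment),
              sem = if (n() > 1) stats::sd(.data$moment) / sqrt(n()) else 0,
              n = n(), .groups = "drop") %>%
    filter(.data$n >= min_n) %>%
    arrange(.data$position)
}

#' Consensus TMD sequence
#'
#' The most abundant residue at each requested aligned position; ties are
#' broken lexicographically (alphabetically first residue wins).
#'
#' @param freq A `tmd_freq` matrix from [frequency_matrix()].
#' @param positions Positions to include, in order; default all positions in
#'   `freq`.
#' @return A single consensus string.
#' @export
consensus_tmd <- function(freq, positions = NULL) {
  if (is.null(positions)) positions <- sort(unique(freq$position))
  missing <- setdiff(positions, freq$position[freq$n > 0])
  if (length(missing) > 0) {
    abort(paste0("no counts at position(s): ", paste(missing, collapse = ", ")))
  }
  picks <- freq %>%
    filter(.data$position %in% positions) %>%
    group_by(.data$position) %>%
    arrange(dplyr::desc(.data$freq), .data$residue, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  paste(picks$residue[match(positions, picks$position)], collapse = "")
}
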