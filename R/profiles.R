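# Positional analytics over cytosolic-edge-aligned TMD sets.

#' Positional residue-frequency matrix
#'
#' For every aligned position, the fraction of proteins carrying each of the
#' 20 residues there, normalized over the proteins that have a residue at
#' that position (long flanks contribute fewer proteins at distal
#' positions). Fractions at a position sum to one.
#'
#' @param aligned A `tmd_aligned` tibble from [align_tmds()].
#' @param positions Optional integer vector restricting the positions
#'   reported; default all positions present.
#' @param min_n Minimum number of contributing proteins for a position to be
#'   reported (default 1).
#' @return A long tibble of class `tmd_freq` with columns `position`,
#'   `residue`, `freq`, `n` (the full 20-residue grid per position, zeros
#'   included).
#' @export
frequency_matrix <- function(aligned, positions = NULL, min_n = 1) {
  if (nrow(aligned) == 0) abort("frequency_matrix: empty aligned set")
  dat <- aligned
  if (!is.null(positions)) dat <- filter(dat, .data$position %in% positions)
  out <- dat %>%
    count(.data$position, .data$residue, name = "k") %>%
    group_by(.data$position) %>%
    mutate(n = sum(.data$k), freq = .data$k / .data$n) %>%
    ungroup() %>%
    filter(.data$n >= min_n) %>%
    select("position", "residue", "freq", "n") %>%
    tidyr::complete(.data$position, residue = AA_ALPHABET,
                    fill = list(freq = 0)) %>%
    group_by(.data$position) %>%
    mutate(n = max(.data$n, na.rm = TRUE)) %>%
    ungroup() %>%
    arrange(.data$position, .data$residue)
  class(out) <- c("tmd_freq", class(out))
  out
}

#' Positional mean-property profile
#'
#' Mean and standard error of a per-residue property (hydropathy in
#' kcal/mol, or residue volume in cubic Angstrom) over the proteins
#' contributing a residue at each aligned position.
#'
#' @param aligned A `tmd_aligned` tibble.
#' @param property A [hydrophobicity_scale()], `"ges"`/`"ww"`/`"bio"`,
#'   `"volume"`, or any complete named per-residue numeric vector.
#' @param min_n Positions with fewer contributing proteins are dropped
#'   (default 10), which trims the noisy tails where only a few long flanks
#'   remain.
#' @return A tibble of class `tmd_profile` with columns `position`, `mean`,
#'   `sem`, `n`.
#' @export
positional_profile <- function(aligned, property, min_n = 10) {
  if (nrow(aligned) == 0) abort("positional_profile: empty aligned set")
  vals <- resolve_property(property)
  absent <- setdiff(unique(aligned$residue), names(vals))
  if (length(absent) > 0) {
    abort(paste0("property table lacks residue(s): ", paste(absent, collapse = ", ")))
  }
  out <- aligned %>%
    mutate(value = unname(vals[.data$residue])) %>%
    group_by(.data$position) %>%
    summarise(mean = mean(.data$value),
              sem = if (n() > 1) stats::sd(.data$value) / sqrt(n()) else 0,
              n = n(), .groups = "drop") %>%
    filter(.data$n >= min_n) %>%
    arrange(.data$position)
  class(out) <- c("tmd_profile", class(out))
  out
}

#' Per-position two-sample comparison of property profiles
#'
#' Classic two-sample t test (pooled variance by default, Welch optional)
#' of a per-residue property between two aligned sets, at every position
#' where both sets have at least `min_n` observations. No multiple-testing
#' correction is applied across positions: p-values are reported raw, one
#' test per position, as is conventional for positional TMD profiles.
#'
#' @param set_a,set_b `tmd_aligned` tibbles.
#' @param property As in [positional_profile()].
#' @param var_equal Pooled-variance t test when `TRUE` (default); Welch
#'   when `FALSE`.
#' @param min_n Minimum observations per side at a position; positions with
#'   fewer than 2 on either side get `NA` statistics rather than an error.
#' @return Tibble with `position`, `mean_a`, `mean_b`, `diff` (a minus b),
#'   `n_a`, `n_b`, `statistic`, `df`, `p_value`.
#' @export
compare_profiles <- function(set_a, set_b, property, var_equal = TRUE, min_n = 2) {
  vals <- resolve_property(property)
  prep <- function(s) {
    s %>%
      mutate(value = unname(vals[.data$residue])) %>%
      select("position", "value")
  }
  a <- prep(set_a); b <- prep(set_b)
  pos <- intersect(unique(a$position), unique(b$position))
  rows <- purrr::map(sort(pos), function(p) {
    xa <- a$value[a$position == p]
    xb <- b$value[b$position == p]
    base <- tibble(position = p, mean_a = mean(xa), mean_b = mean(xb),
                   diff = mean(xa) - mean(xb),
                   n_a = length(xa), n_b = length(xb))
    if (length(xa) < max(2, min_n) || length(xb) < max(2, min_n) ||
        (stats::sd(xa) == 0 && stats::sd(xb) == 0)) {
      # identical constant samples: t = 0, p = 1; under-populated: undefined
      if (length(xa) >= 2 && length(xb) >= 2 &&
          isTRUE(all.equal(mean(xa), mean(xb)))) {
        return(mutate(base, statistic = 0, df = NA_real_, p_value = 1))
      }
      return(mutate(base, statistic = NA_real_, df = NA_real_, p_value = NA_real_))
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    mutate(base, statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  })
  bind_rows(rows)
}

#' Compare two hydrophobic-length distributions
#'
#' Single two-sample t test on the raw hydrophobic lengths of two annotated
#' sets.
#'
#' @param ann_a,ann_b `tmd_annotation` tibbles.
#' @param var_equal Pooled variance when `TRUE` (default).
#' @return One-row tibble with means, difference, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_lengths <- function(ann_a, ann_b, var_equal = TRUE) {
  xa <- ann_a$hydrophobic_length
  xb <- ann_b$hydrophobic_length
  tt <- stats::t.test(xa, xb, var.equal = var_equal)
  tibble(mean_a = mean(xa), mean_b = mean(xb), diff = mean(xa) - mean(xb),
         n_a = length(xa), n_b = length(xb),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Hydrophobic-length distribution
#'
#' Exact histogram and mean of the hydrophobic lengths in an annotated set.
#'
#' @param annotations A `tmd_annotation` tibble.
#' @return A tibble of class `tmd_lengths` with columns `length`, `count`,
#'   and attributes `mean` and `n`.
#' @export
length_distribution <- function(annotations) {
  if (nrow(annotations) == 0) abort("length_distribution: empty annotation set")
  out <- annotations %>%
    count(length = .data$hydrophobic_length, name = "count") %>%
    arrange(.data$length)
  attr(out, "mean") <- mean(annotations$hydrophobic_length)
  attr(out, "n") <- nrow(annotations)
  class(out) <- c("tmd_lengths", class(out))
  out
}

#' @export
print.tmd_lengths <- function(x, ...) {
  cat(sprintf("Hydrophobic length distribution: n = %d, mean = %.3f residues\n",
              attr(x, "n"), attr(x, "mean")))
  NextMethod()
}
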