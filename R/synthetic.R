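# Synthetic organelle-labeled bitopic proteins.
#
# Each preset emulates the statistical structure the analyses assume:
# organelle-specific hydrophobic-core length distributions (ER/Golgi short,
# TGN/endosomes intermediate, plasma membrane long), volume-biased
# outer-leaflet compositions (PM outer half enriched in small residues,
# Golgi in large ones), positive-inside charged cytosolic flanks, and an
# optional serine-rich lumenal linker for Golgi-like sets. Sequences are
# built in bilayer orientation (cytosol -> exoplasm) and then written N->C
# or C->N according to the drawn topology, so every pipeline stage
# (scanning, orientation, profiling, classification) is exercised.
#
# The membrane-water interface is modelled explicitly as a three-residue
# gate on each side of the core -- Ser/Thr against the core, then a small
# mildly polar residue, then a strongly polar one -- while the first and
# last core residues are drawn from the strongly hydrophobic subset
# (L/I/V/F). This gives the sharp hydropathy transition at the core
# boundary that real single-pass TMDs show and that edge scanning relies
# on; without it the scanned edge is not well defined even in principle.

norm1 <- function(x) x / sum(x)

# hydrophobic background: the symmetric reference core composition
CORE_BACKGROUND <- norm1(c(L = .30, I = .15, V = .12, F = .10, A = .12,
                           M = .04, G = .06, S = .06, T = .04, C = .01))

# ER cores are symmetric and less fiercely hydrophobic, with a marked
# Cys/Ser/Thr admixture (ER-resident TMDs are the least hydrophobic set)
ER_CORE <- norm1(c(L = .24, I = .12, V = .10, F = .07, A = .12, M = .03,
                   G = .08, S = .10, T = .06, C = .08))

# inner (cytosolic) halves: the leaflet asymmetry runs both ways -- the PM
# inner half is enriched in large residues (leucine favoured inner), the
# Golgi inner half in small ones; ER stays symmetric and TGN/endosomes
# carry a mild small-residue shift on both halves
INNER_COMPOSITIONS <- list(
  er    = ER_CORE,
  golgi = norm1(c(L = .18, I = .09, V = .18, F = .04, A = .18,
                  M = .01, G = .12, S = .13, T = .06, C = .01)),
  tgn   = norm1(c(L = .21, I = .10, V = .17, F = .05, A = .16,
                  M = .02, G = .11, S = .11, T = .06, C = .01)),
  pm    = norm1(c(L = .40, I = .19, V = .07, F = .15, A = .07,
                  M = .05, G = .02, S = .02, T = .02, C = .01))
)

# outer (exoplasmic) halves: PM and TGN/endosomes shifted toward small
# residues (G, A, S, V), Golgi toward large ones (F, L, I, W)
OUTER_COMPOSITIONS <- list(
  er    = ER_CORE,
  golgi = norm1(c(L = .36, I = .18, V = .05, F = .19, A = .05,
                  M = .04, G = .01, S = .01, T = .01, C = .01, W = .09)),
  tgn   = norm1(c(L = .18, I = .09, V = .20, F = .05, A = .15,
                  M = .02, G = .12, S = .13, T = .05, C = .01)),
  pm    = norm1(c(L = .12, I = .06, V = .28, F = .04, A = .15,
                  M = .01, G = .12, S = .12, T = .06, C = .04))
)

# cytosolic flank: K/R enrichment level varies by organelle (positive-inside)
cyt_flank_comp <- function(kr) {
  rest <- norm1(c(N = .12, Q = .10, S = .12, T = .06, G = .08, P = .08,
                  D = .06, E = .06, H = .03, A = .01, L = .01)) * (1 - kr)
  c(K = 0.6 * kr, R = 0.4 * kr, rest)
}

EXO_FLANK_COMPOSITIONS <- list(
  er    = norm1(c(N = .14, Q = .12, S = .14, T = .06, G = .08, P = .10,
                  D = .12, E = .12, H = .04, A = .02, K = .04, R = .02)),
  golgi = norm1(c(S = .40, T = .10, N = .10, Q = .08, G = .02, P = .10,
                  D = .08, E = .06, H = .04, A = .02)),  # serine-rich linker
  tgn   = norm1(c(S = .22, T = .08, N = .12, Q = .10, G = .06, P = .08,
                  D = .10, E = .10, H = .04, A = .02, K = .05, R = .03)),
  pm    = norm1(c(N = .13, Q = .10, S = .16, T = .06, G = .08, P = .08,
                  D = .11, E = .11, H = .04, A = .02, K = .06, R = .05))
)

# three-residue interface gate flanking the core on either side: Ser/Thr
# against the core, then a small/mildly polar residue, then a strongly
# polar one -- the sharp hydropathy step the scanning algorithm detects
GATE1 <- c(S = 0.7, T = 0.3)
GATE2 <- c(S = .30, T = .20, P = .30, G = .20)
GATE3_CYT <- c(N = .30, Q = .20, K = .20, R = .15, D = .075, E = .075)
GATE3_EXO <- c(N = .35, Q = .30, D = .15, E = .15, H = .05)
STRONG_CORE <- c("L", "I", "V", "F")              # core boundary residues

PRESETS <- list(
  `fungal-er` = list(organelle = "ER", core_mean = 20, kr = 0.25,
                     outer = "er", exo = "er",
                     topology_mix = c(I = .30, II = .60, III = .10)),
  `fungal-golgi` = list(organelle = "Golgi", core_mean = 19, kr = 0.30,
                        outer = "golgi", exo = "golgi",
                        topology_mix = c(I = 0, II = 1, III = 0)),
  `fungal-tgn` = list(organelle = "TGN/endosomes", core_mean = 22, kr = 0.40,
                      outer = "tgn", exo = "tgn",
                      topology_mix = c(I = .40, II = .50, III = .10)),
  `fungal-pm` = list(organelle = "PM", core_mean = 26, kr = 0.50,
                     outer = "pm", exo = "pm",
                     topology_mix = c(I = .90, II = .10, III = 0)),
  `vert-golgi` = list(organelle = "Golgi", core_mean = 21, kr = 0.30,
                      outer = "golgi", exo = "golgi", damp = 0.5,
                      topology_mix = c(I = .20, II = .80, III = 0)),
  `vert-pm` = list(organelle = "PM", core_mean = 24, kr = 0.40,
                   outer = "pm", exo = "pm", damp = 0.5,
                   topology_mix = c(I = .60, II = .30, III = .10))
)

#' Synthetic organelle presets
#'
#' `organelle_presets()` lists the available preset names;
#' `organelle_preset()` materializes one as a parameter object. The fungal
#' presets place the mean hydrophobic core lengths at Golgi 19, ER 20,
#' TGN/endosomes 22 and plasma membrane 26 residues (discretized normal,
#' sd 1.5, truncated at +/-4), reproducing the short-Golgi / long-PM
#' ordering and the roughly 8-residue fungal Golgi-to-PM gap expected from
#' ~12 Angstrom of bilayer thickness difference at ~1.5 Angstrom per helix
#' residue. Vertebrate presets (`vert-*`) narrow the gap and damp the
#' compositional asymmetry by half.
#'
#' @param name One of `organelle_presets()`.
#' @return An object of class `organelle_preset`: organelle label, core
#'   length distribution, inner/outer core compositions, flank models and
#'   topology mix.
#' @export
organelle_preset <- function(name) {
  if (!name %in% names(PRESETS)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(PRESETS), collapse = ", ")))
  }
  p <- PRESETS[[name]]
  outer <- OUTER_COMPOSITIONS[[p$outer]]
  inner <- INNER_COMPOSITIONS[[p$outer]]
  if (!is.null(p$damp)) {  # shrink compositional shifts toward background
    blend <- function(comp) {
      full <- setNames(numeric(length(union(names(comp), names(CORE_BACKGROUND)))),
                       union(names(comp), names(CORE_BACKGROUND)))
      full[names(CORE_BACKGROUND)] <- CORE_BACKGROUND
      full[names(comp)] <- full[names(comp)] + p$damp * (comp - full[names(comp)])
      norm1(full[full > 0])
    }
    outer <- blend(outer)
    inner <- blend(inner)
  }
  structure(
    list(name = name, organelle = p$organelle,
         core_mean = p$core_mean, core_sd = 1.5, core_halfwidth = 4,
         inner_composition = inner,
         outer_composition = outer,
         cytosolic_flank = list(length_range = c(10L, 22L),
                                kr = p$kr,
                                composition = cyt_flank_comp(p$kr),
                                gate1 = GATE1, gate2 = GATE2, gate3 = GATE3_CYT),
         exoplasmic_flank = list(length_range = c(10L, 30L),
                                 composition = EXO_FLANK_COMPOSITIONS[[p$exo]],
                                 gate1 = GATE1, gate2 = GATE2, gate3 = GATE3_EXO),
         topology_mix = p$topology_mix),
    class = "organelle_preset"
  )
}

#' @rdname organelle_preset
#' @export
organelle_presets <- function() names(PRESETS)

#' @export
print.organelle_preset <- function(x, ...) {
  cat(sprintf("<organelle_preset: %s> organelle %s, core %g +/- %g residues, cytosolic K/R %.0f%%\n",
              x$name, x$organelle, x$core_mean, x$core_sd,
              100 * x$cytosolic_flank$kr))
  invisible(x)
}

draw <- function(n, comp) sample(names(comp), n, replace = TRUE, prob = comp)

draw_core_length <- function(preset) {
  l <- round(rnorm(1, preset$core_mean, preset$core_sd))
  max(12L, as.integer(pmin(pmax(l, preset$core_mean - preset$core_halfwidth),
                           preset$core_mean + preset$core_halfwidth)))
}

# flank residues ordered adjacent-to-core first
draw_flank <- function(model) {
  len <- sample(seq(model$length_range[1], model$length_range[2]), 1)
  c(draw(1, model$gate1), draw(1, model$gate2), draw(1, model$gate3),
    draw(len - 3, model$composition))
}

#' Sample one synthetic bitopic protein
#'
#' Draws topology, hydrophobic-core length, inner-half residues from the
#' preset's inner composition, outer-half residues from its outer
#' composition and flanks from its flank models, then writes the sequence
#' N->C for type II or C->N (reversed) for types I/III. The guide TMD
#' interval is the true core interval with each end independently perturbed
#' by up to +/-2 residues, to exercise edge refinement. The ground truth
#' (exact core interval) is attached for recovery tests.
#'
#' @param preset An [organelle_preset()].
#' @param id Protein id to assign.
#' @param seed Optional integer seed (draws from the ambient RNG stream
#'   when `NULL`, as when called from [sample_dataset()]).
#' @return A one-row protein tibble with attribute `truth`: a tibble of
#'   `id`, `true_start`, `true_end`, `organelle`, `preset`, `topology`.
#' @export
sample_protein <- function(preset, id = "synthetic_1", seed = NULL) {
  run <- function() {
    topology <- draw(1, preset$topology_mix)
    l_core <- draw_core_length(preset)
    n_in <- floor(l_core / 2)
    inner <- draw(n_in, preset$inner_composition)
    outer <- draw(l_core - n_in, preset$outer_composition)
    # strongly hydrophobic boundary residues anchor the scanned edges
    inner[1] <- draw(1, norm1(preset$inner_composition[STRONG_CORE]))
    outer[length(outer)] <- draw(1, norm1(preset$outer_composition[STRONG_CORE]))
    cyt <- draw_flank(preset$cytosolic_flank)   # adjacent first
    exo <- draw_flank(preset$exoplasmic_flank)
    oriented <- c(rev(cyt), inner, outer, exo)  # cytosol -> exoplasm
    n_tot <- length(oriented)
    if (topology == "II") {
      s <- oriented
      true_start <- length(cyt) + 1L
    } else {
      s <- rev(oriented)
      true_start <- length(exo) + 1L
    }
    true_end <- true_start + l_core - 1L
    g_start <- min(max(1L, true_start + sample(-2:2, 1)), true_end - 9L)
    g_end <- max(min(n_tot, true_end + sample(-2:2, 1)), g_start + 9L)
    protein <- tibble(id = id, sequence = paste(s, collapse = ""),
                      topology = topology, organelle = preset$organelle,
                      tmd_start = as.integer(g_start), tmd_end = as.integer(g_end),
                      species = NA_character_)
    attr(protein, "truth") <- tibble(id = id,
                                     true_start = as.integer(true_start),
                                     true_end = as.integer(true_end),
                                     core_length = l_core,
                                     organelle = preset$organelle,
                                     preset = preset$name, topology = topology)
    protein
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Sample a synthetic organelle dataset
#'
#' `n` independent proteins from one preset, reproducible from `seed`.
#'
#' @param preset An [organelle_preset()] or preset name.
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @return Protein tibble with attribute `truth` (one row per protein, see
#'   [sample_protein()]).
#' @export
sample_dataset <- function(preset, n, seed = NULL) {
  if (is.character(preset)) preset <- organelle_preset(preset)
  if (n < 1) abort("sample_dataset: n must be >= 1")
  prefix <- gsub("[^a-zA-Z0-9]", "_", preset$name)
  run <- function() {
    lapply(seq_len(n), function(i) sample_protein(preset, id = sprintf("%s_%04d", prefix, i)))
  }
  ps <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  out <- bind_rows(ps)
  attr(out, "truth") <- bind_rows(lapply(ps, attr, "truth"))
  out
}

#' Generate a family of near-duplicate proteins
#'
#' Produces `n` mutated copies of a base protein whose identity to the base
#' over the TMD region (guide interval plus `flank` residues per side) is
#' within 5 percentage points of `target_identity`, verified internally
#' with [pairwise_identity()]. Used to exercise redundancy reduction:
#' a high-identity family collapses to one representative, a low-identity
#' one survives intact. Substitution-only mutation preserves coordinates.
#'
#' @param base_protein One-row protein tibble.
#' @param n Family size.
#' @param target_identity Target identity in `(0, 1]`.
#' @param seed Integer seed.
#' @param flank Flank width of the identity region (default 10).
#' @return Protein tibble of `n` rows with ids `<base id>_v1..n`.
#' @export
make_redundant_family <- function(base_protein, n, target_identity, seed = NULL,
                                  flank = 10) {
  if (target_identity <= 0 || target_identity > 1) {
    abort("target_identity must be in (0, 1]")
  }
  base <- base_protein[1, , drop = FALSE]
  lo <- max(1L, base$tmd_start - as.integer(flank))
  hi <- min(nchar(base$sequence), base$tmd_end + as.integer(flank))
  base_region <- substr(base$sequence, lo, hi)
  region_counts <- table(factor(strsplit(base_region, "")[[1]], levels = AA_ALPHABET))
  # substitute with residues rare in the base region so low identities are
  # reachable despite the permissive gap scheme
  repl_pool <- names(sort(region_counts))[1:8]
  mutate_one <- function() {
    s <- strsplit(base$sequence, "")[[1]]
    if (target_identity >= 0.999) return(paste(s, collapse = ""))
    order_pos <- sample(lo:hi)
    k <- 0
    for (p in order_pos) {
      ident <- pairwise_identity(base_region,
                                 paste(s[lo:hi], collapse = ""))
      if (ident <= target_identity + 0.05) break
      s[p] <- sample(setdiff(repl_pool, s[p]), 1)
      k <- k + 1
    }
    ident <- pairwise_identity(base_region, paste(s[lo:hi], collapse = ""))
    if (abs(ident - target_identity) > 0.05) {
      abort(sprintf("target identity %.2f unattainable (reached %.2f)",
                    target_identity, ident))
    }
    paste(s, collapse = "")
  }
  run <- function() vapply(seq_len(n), function(i) mutate_one(), character(1))
  seqs <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  out <- base[rep(1, n), , drop = FALSE]
  out$id <- paste0(base$id, "_v", seq_len(n))
  out$sequence <- seqs
  out
}
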