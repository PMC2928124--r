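test_that("leaflet preference is zero for mirror-identical halves and attains
           its bounds", {
  # identical half compositions -> no preference for any residue
  al <- make_aligned(c(a = paste0("LAVG", "LAVG")))
  lp <- leaflet_preference(al)
  expect_true(all(lp$ratio[!is.na(lp$ratio)] == 0))
  # a residue confined to one half attains +/- 1
  al2 <- make_aligned(c(a = paste0("WLLL", "GLLL")))
  lp2 <- leaflet_preference(al2)
  expect_equal(lp2$ratio[lp2$residue == "W"], -1)  # inner only
  expect_equal(lp2$ratio[lp2$residue == "G"], 1)   # outer only
  expect_true(all(abs(lp2$ratio[!is.na(lp2$ratio)]) <= 1))
})

test_that("leaflet ratios reproduce direct arithmetic", {
  # inner: 1 A of 10 (0.1), outer: 2 A of 10 (0.2) -> (0.2-0.1)/0.3 = 1/3
  core <- paste0("A", strrep("L", 9), "AA", strrep("L", 8))
  lp <- leaflet_preference(make_aligned(c(a = core)))
  expect_equal(lp$ratio[lp$residue == "A"], 1 / 3)
  expect_equal(lp$ratio[lp$residue == "L"], (0.8 - 0.9) / 1.7)
})

test_that("leaflet ratios negate when the halves are swapped", {
  h1 <- "ALVGWSAL"; h2 <- "LLIVFFMT"
  lp_ab <- leaflet_preference(make_aligned(c(x = paste0(h1, h2))))
  lp_ba <- leaflet_preference(make_aligned(c(x = paste0(h2, h1))))
  ok <- !is.na(lp_ab$ratio)
  expect_equal(lp_ab$ratio[ok], -lp_ba$ratio[ok])
})

test_that("odd core lengths assign the midpoint residue to the outer half", {
  # length 5: inner = positions 1..2, outer = 3..5
  lp <- leaflet_preference(make_aligned(c(a = "LLGGG")))
  expect_equal(lp$ratio[lp$residue == "G"], 1)
  expect_equal(lp$ratio[lp$residue == "L"], -1)
})

test_that("organelle sets show the expected leaflet sign pattern", {
  signs <- function(preset) {
    prot <- sample_dataset(preset, 99, seed = 13)
    al <- align_tmds(prot, annotate_tmds(prot))
    lp <- leaflet_preference(al)
    setNames(lp$ratio, lp$residue)
  }
  pm <- signs("fungal-pm")
  golgi <- signs("fungal-golgi")
  # PM: small residues enriched in the outer leaflet, large ones inner
  expect_true(all(pm[c("G", "A", "S", "V")] > 0))
  expect_true(all(pm[c("F", "I", "L")] < 0))
  # Golgi: the reverse
  expect_true(all(golgi[c("G", "A", "S", "V")] < 0))
  expect_true(all(golgi[c("F", "I", "L")] > 0))
})

test_that("size moment matches the closed-form homopolymer value to 1e-9", {
  v <- residue_volumes()
  sm <- size_moment(strrep("L", 15))
  geom <- Mod(sum(exp(1i * (0:6) * 100 * pi / 180)))
  expect_true(all(abs(sm$moment - v[["L"]] * geom) < 1e-9))
  expect_equal(sm$position, 4:12)
  # zero-volume residues give exactly zero moment
  zero <- setNames(rep(0, 20), names(v))
  expect_true(all(size_moment(strrep("L", 10), volumes = zero)$moment == 0))
})

test_that("size moment equals a complex-arithmetic oracle and peaks at GXXXG", {
  seqs <- c(strrep("L", 12),
            paste0(strrep("L", 7), "G", "LLL", "G", strrep("L", 8)),
            "WGAVLFIMSTCY")
  v <- residue_volumes()
  for (s in seqs) {
    res <- strsplit(s, "")[[1]]
    expect_equal(size_moment(s)$moment, unname(size_moment_oracle(res, v)),
                 tolerance = 1e-12)
  }
  # the GXXXG motif flattens one helix face: local maximum above baseline
  gx <- paste0(strrep("L", 7), "G", "LLL", "G", strrep("L", 8))
  sm <- size_moment(gx)
  baseline <- v[["L"]] * Mod(sum(exp(1i * (0:6) * 100 * pi / 180)))
  expect_gt(max(sm$moment), baseline)
  peak_pos <- sm$position[which.max(sm$moment)]
  expect_true(peak_pos %in% 8:12)  # at the motif
})

test_that("size moment skips windows that extend past available residues", {
  expect_equal(nrow(size_moment(strrep("L", 6))), 0)
  expect_equal(nrow(size_moment(strrep("L", 7))), 1)
  # set-level profile averages per-protein moments
  prot <- sample_dataset("fungal-er", 15, seed = 2)
  al <- align_tmds(prot, annotate_tmds(prot))
  smp <- size_moment_profile(al, min_n = 5)
  expect_true(all(smp$mean >= 0))
  expect_true(all(smp$n >= 5))
})

test_that("consensus sequences take the most abundant residue with
           lexicographic ties", {
  al <- make_aligned(c(a = "LIVF"))
  expect_equal(consensus_tmd(frequency_matrix(al)), "LIVF")
  tie <- make_aligned(c(a = "AL", b = "VL"))
  expect_equal(consensus_tmd(frequency_matrix(tie)), "AL")
  expect_error(consensus_tmd(frequency_matrix(al), positions = 1:9),
               "no counts")
})

test_that("a matrix built from copies of the printed Golgi consensus returns
           that string", {
  golgi_consensus <- "RRRRRLLLAALLLLLLLLLSSSSS"
  al <- make_aligned(setNames(rep(golgi_consensus, 5), paste0("c", 1:5)))
  fm <- frequency_matrix(al)
  expect_equal(consensus_tmd(fm, positions = 1:24), golgi_consensus)
})

test_that("the printed PM consensus has a longer hydrophobic core than the
           printed Golgi consensus", {
  golgi <- make_protein("RRRRRLLLAALLLLLLLLLSSSSS", id = "golgi",
                        tmd_start = 6, tmd_end = 19)
  pm <- make_protein("KKRRRLFFFLILLLLLLVVVVGVVAAIGGSSGS", id = "pm",
                     tmd_start = 6, tmd_end = 30)
  len <- function(p) annotate_tmd(p)$hydrophobic_length
  expect_gt(len(pm), len(golgi))
})
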