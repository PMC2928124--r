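test_that("frequency matrices normalize per position over contributing proteins", {
  al <- make_aligned(c(a = "LLVA", b = "LLVA", c = "LLVA"))
  fm <- frequency_matrix(al)
  expect_s3_class(fm, "tmd_freq")
  expect_equal(fm$freq[fm$position == 1 & fm$residue == "L"], 1.0)
  sums <- tapply(fm$freq, fm$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # two proteins differing at one position split 0.5/0.5
  al2 <- make_aligned(c(a = "LLLLA", b = "LLLLV"))
  fm2 <- frequency_matrix(al2)
  expect_equal(fm2$freq[fm2$position == 5 & fm2$residue %in% c("A", "V")],
               c(0.5, 0.5))
  expect_error(frequency_matrix(al[0, ]), "empty")
})

test_that("sampled frequencies recover the generator composition", {
  prot <- sample_dataset("fungal-golgi", 500, seed = 17)
  al <- align_tmds(prot, annotate_tmds(prot))
  fm <- frequency_matrix(al)
  inner <- organelle_preset("fungal-golgi")$inner_composition
  # interior inner-half positions draw iid from the inner composition
  for (p in 3:8) {
    obs <- fm$freq[fm$position == p]
    names(obs) <- fm$residue[fm$position == p]
    expect_true(all(abs(obs[names(inner)] - inner) < 0.05))
  }
})

test_that("positional profiles compute exact means and SEMs", {
  al <- make_aligned(c(a = "LLLL", b = "LLLL"))
  pr <- positional_profile(al, "volume", min_n = 1)
  expect_true(all(pr$mean == residue_volumes()[["L"]]))
  expect_true(all(pr$sem == 0))
  # mixed positions equal the abundance-weighted average
  al2 <- make_aligned(c(a = "AG", b = "AV", c = "AV"))
  pr2 <- positional_profile(al2, "volume", min_n = 1)
  v <- residue_volumes()
  expect_equal(pr2$mean[pr2$position == 2],
               mean(v[c("G", "V", "V")]))
  expect_error(positional_profile(al2, c(A = 1, G = 2)), "missing residues")
})

test_that("profiles equal the property-weighted contraction of the frequency
           matrix", {
  prot <- sample_dataset("fungal-tgn", 30, seed = 23)
  al <- align_tmds(prot, annotate_tmds(prot))
  fm <- frequency_matrix(al)
  pr <- positional_profile(al, "volume", min_n = 1)
  v <- residue_volumes()
  contracted <- tapply(fm$freq * v[fm$residue], fm$position, sum)
  expect_equal(pr$mean, as.numeric(contracted[as.character(pr$position)]))
})

test_that("per-position t tests match the textbook formula to 1e-10", {
  set.seed(5)
  # property values arise from residues; use volumes as the property and
  # random residue draws as the two samples
  res_pool <- c("A", "G", "L", "W", "V", "S")
  a <- make_aligned(setNames(replicate(25, paste(sample(res_pool, 12, TRUE),
                                                 collapse = "")),
                             paste0("a", 1:25)))
  b <- make_aligned(setNames(replicate(30, paste(sample(res_pool, 12, TRUE),
                                                 collapse = "")),
                             paste0("b", 1:30)))
  v <- residue_volumes()
  for (pooled in c(TRUE, FALSE)) {
    cmp <- compare_profiles(a, b, "volume", var_equal = pooled)
    for (p in c(1, 5, 12)) {
      xa <- v[a$residue[a$position == p]]
      xb <- v[b$residue[b$position == p]]
      expect_equal(cmp$p_value[cmp$position == p],
                   t_test_oracle(xa, xb, pooled = pooled), tolerance = 1e-10)
    }
  }
})

test_that("identical sets compare with t = 0 and p = 1, sparse positions are NA", {
  al <- make_aligned(c(a = "LLLL", b = "LLLL"))
  cmp <- compare_profiles(al, al, "volume")
  expect_true(all(cmp$statistic == 0))
  expect_true(all(cmp$p_value == 1))
  one <- make_aligned(c(a = "LLLL"))
  cmp2 <- compare_profiles(one, al, "volume", min_n = 2)
  expect_true(all(is.na(cmp2$p_value)))
  # symmetry up to the sign of the difference
  prot_a <- sample_dataset("fungal-er", 15, seed = 3)
  prot_b <- sample_dataset("fungal-pm", 15, seed = 3)
  ala <- align_tmds(prot_a, annotate_tmds(prot_a))
  alb <- align_tmds(prot_b, annotate_tmds(prot_b))
  ab <- compare_profiles(ala, alb, "volume")
  ba <- compare_profiles(alb, ala, "volume")
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$diff, -ba$diff)
})

test_that("Golgi and PM volume profiles overlap near the cytosol and diverge
           in the exoplasmic half", {
  golgi <- sample_dataset("fungal-golgi", 99, seed = 19)
  pm <- sample_dataset("fungal-pm", 99, seed = 19)
  alg <- align_tmds(golgi, annotate_tmds(golgi))
  alp <- align_tmds(pm, annotate_tmds(pm))
  cmp <- compare_profiles(alg, alp, "volume")
  exo <- cmp[cmp$position %in% 14:17, ]
  expect_true(all(exo$diff > 0))          # Golgi larger residues outside
  expect_true(all(exo$p_value < 0.01))
  # within each set the halves trend in opposite directions: mean residue
  # volume falls toward the exoplasmic side for PM and rises for Golgi
  prof_g <- positional_profile(alg, "volume")
  prof_p <- positional_profile(alp, "volume")
  half_mean <- function(pr, pos) mean(pr$mean[pr$position %in% pos])
  expect_gt(half_mean(prof_p, 2:6), half_mean(prof_p, 15:19))
  expect_lt(half_mean(prof_g, 2:6), half_mean(prof_g, 14:18))
})

test_that("length distributions are exact and ordered across organelles", {
  ann <- tibble::tibble(id = c("a", "b", "c"), topology = "II",
                        organelle = "X", cytosolic_edge = 1L,
                        exoplasmic_edge = c(20L, 20L, 24L),
                        hydrophobic_length = c(20L, 20L, 24L), scale = "ges")
  ld <- length_distribution(ann)
  expect_equal(attr(ld, "mean"), mean(c(20, 20, 24)))
  expect_equal(ld$count[ld$length == 20], 2)
  expect_equal(ld$count[ld$length == 24], 1)
  expect_equal(attr(length_distribution(ann[1, ]), "mean"), 20)
  # PM TMDs run longer than Golgi TMDs
  golgi <- annotate_tmds(sample_dataset("fungal-golgi", 99, seed = 29))
  pm <- annotate_tmds(sample_dataset("fungal-pm", 99, seed = 29))
  expect_gt(attr(length_distribution(pm), "mean"),
            attr(length_distribution(golgi), "mean"))
  lc <- compare_lengths(pm, golgi)
  expect_lt(lc$p_value, 1e-10)
  expect_gt(lc$diff, 0)
})
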