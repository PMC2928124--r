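# Shared fixtures and independent oracles. Everything here is deliberately
# written without reusing package internals, so the tests cross-check the
# implementation rather than mirroring it.

make_protein <- function(sequence, id = "p1", topology = "II",
                         organelle = "X", tmd_start, tmd_end) {
  tibble::tibble(id = id, sequence = sequence, topology = topology,
                 organelle = organelle, tmd_start = as.integer(tmd_start),
                 tmd_end = as.integer(tmd_end), species = NA_character_)
}

# a clean protein whose hydrophobic core is exactly `core`: flanks step
# from Ser/Thr through a mild residue to strongly polar, then charged
clean_protein <- function(core = strrep("L", 20), id = "p1",
                          topology = "II", organelle = "X",
                          cyt = "KKKKKNPS", exo = "SPNKKKKK") {
  seq_fwd <- paste0(cyt, core, exo)
  start <- nchar(cyt) + 1L
  end <- nchar(cyt) + nchar(core)
  if (topology != "II") {
    n <- nchar(seq_fwd)
    seq_fwd <- paste(rev(strsplit(seq_fwd, "")[[1]]), collapse = "")
    new_start <- n - end + 1L
    end <- n - start + 1L
    start <- new_start
  }
  make_protein(seq_fwd, id = id, topology = topology, organelle = organelle,
               tmd_start = start, tmd_end = end)
}

# hand-build an aligned set: `cores` is a named character vector of core
# strings (position 1..nchar), optional cytosolic/exoplasmic flank strings
# occupy positions <= 0 (last character at position 0) and > core length
make_aligned <- function(cores, cyt = NULL, exo = NULL, organelle = "X") {
  ids <- names(cores)
  rows <- lapply(ids, function(i) {
    chars <- function(s) strsplit(s, "")[[1]]
    core <- chars(cores[[i]])
    fc <- if (is.null(cyt)) character(0) else chars(cyt)
    fe <- if (is.null(exo)) character(0) else chars(exo)
    res <- c(fc, core, fe)
    pos <- c(seq_len(length(fc)) - length(fc),          # ..., -1, 0
             seq_along(core),
             length(core) + seq_len(length(fe)))
    tibble::tibble(id = i, organelle = organelle, topology = "II",
                   position = pos, residue = res)
  })
  out <- dplyr::bind_rows(rows)
  ann <- tibble::tibble(id = ids, topology = "II", organelle = organelle,
                        cytosolic_edge = 1L,
                        exoplasmic_edge = nchar(cores),
                        hydrophobic_length = nchar(cores),
                        scale = "ges")
  attr(out, "annotations") <- ann
  class(out) <- c("tmd_aligned", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent global-alignment oracle: match 1, mismatch 0, gap -1;
# returns matches / alignment length from a full DP with traceback
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  matches / cols
}

# brute-force single-linkage component count over an identity matrix
single_linkage_count <- function(m, threshold) {
  n <- nrow(m)
  visited <- rep(FALSE, n)
  comps <- 0
  for (s in seq_len(n)) {
    if (visited[s]) next
    comps <- comps + 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (visited[v]) next
      visited[v] <- TRUE
      nb <- which(m[v, ] > threshold & !visited)
      queue <- c(queue, nb)
    }
  }
  comps
}

# textbook two-sample t test (pooled or Welch) returning the p-value
t_test_oracle <- function(x, y, pooled = TRUE) {
  nx <- length(x); ny <- length(y)
  if (pooled) {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- var(x) / nx + var(y) / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / nx)^2 / (nx - 1) + (var(y) / ny)^2 / (ny - 1))
  }
  2 * pt(-abs(tstat), df)
}

# helical size-moment oracle via complex arithmetic
size_moment_oracle <- function(res, volumes, window = 7) {
  v <- volumes[res]
  half <- (window - 1) %/% 2
  vapply((1 + half):(length(res) - half), function(c0) {
    w <- v[(c0 - half):(c0 + half)]
    Mod(sum(w * exp(1i * (seq_len(window) - 1) * 100 * pi / 180)))
  }, numeric(1))
}

fungal_presets <- c("fungal-er", "fungal-golgi", "fungal-tgn", "fungal-pm")

fungal_sets <- function(n, seed) {
  dplyr::bind_rows(lapply(fungal_presets, function(p) sample_dataset(p, n, seed = seed)))
}

fungal_truth <- function(n, seed) {
  dplyr::bind_rows(lapply(fungal_presets,
                          function(p) attr(sample_dataset(p, n, seed = seed), "truth")))
}
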