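uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

random_pwm <- function(w, seed, id = "m", sharp = 2) {
  set.seed(seed)
  m <- matrix(rexp(4 * w)^sharp, w, 4)
  m <- m / rowSums(m)
  apexatlas:::new_pwm(id, m, background = uniform_bg)
}

meme_text <- function() {
  c("MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF onebase", "letter-probability matrix: alength= 4 w= 1",
    "1.000000 0.000000 0.000000 0.000000", "")
}

test_that("MEME parsing applies the pseudocount mix", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme_text(), f)
  pw <- read_pwms(f, pseudocount = 0.01)
  expect_length(pw, 1)
  expect_equal(unname(pw$onebase$mat[1, "A"]), 0.97)
  expect_equal(unname(pw$onebase$mat[1, "C"]), 0.01)
  bad <- sub("1.000000 0", "0.700000 0", meme_text())
  writeLines(bad, f)
  expect_error(read_pwms(f), "sum")
})

test_that("a 51-motif file with a 13-family side table loads fully", {
  pwms <- lapply(1:51, function(i) random_pwm(6, seed = 1000 + i,
                                              id = sprintf("M%02d", i)))
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  fmap <- data.frame(pwm = names(pwms),
                     family = sprintf("F%02d", rep_len(1:13, 51)))
  f <- withr::local_tempfile(fileext = ".meme")
  write_pwms(pwms, f)
  back <- read_pwms(f, pseudocount = 0, family_map = fmap)
  expect_length(back, 51)
  expect_equal(length(unique(vapply(back, `[[`, "", "family"))), 13)
  for (i in c(1, 25, 51))
    expect_lt(max(abs(back[[i]]$mat - pwms[[i]]$mat)), 1e-6)
})

test_that("width-1 calibration at p = 0.25 admits only the best base", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme_text(), f)
  pw <- calibrate_threshold(read_pwms(f)$onebase, p_value = 0.25)
  expect_equal(scan_promoter(pw, "A")$strand, "+")
  expect_equal(scan_promoter(pw, "T")$strand, "-")  # rc of the best base
  for (b in c("C", "G"))
    expect_equal(nrow(scan_promoter(pw, b)), 0)
  expect_error(calibrate_threshold(pw, p_value = 0.7), "0, 0.5")
})

test_that("DP score distribution equals exhaustive enumeration for
           short motifs", {
  for (w in 2:6) {
    pwm <- random_pwm(w, seed = 50 + w)
    pv <- 2 / 4^w                     # reachable tail for every width
    cal <- calibrate_threshold(pwm, p_value = pv)
    dist <- attr(cal, "score_dist")
    expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
    # enumerate all 4^w sequences with the same per-position grid
    grid <- apexatlas:::pwm_score_grid(pwm, 1e4)
    combos <- as.matrix(expand.grid(rep(list(1:4), w)))
    idx <- integer(nrow(combos))
    for (i in seq_len(w)) idx <- idx + grid$idx[i, combos[, i]]
    pr <- rep(1 / 4^w, nrow(combos))
    brute <- vapply(seq_len(grid$range + 1L) - 1L,
                    function(k) sum(pr[idx >= k]), numeric(1))
    expect_equal(dist$tail, brute, tolerance = 1e-12)
    # thresholds agree exactly at grid resolution
    ok <- which(brute <= pv)
    brute_theta <- if (length(ok)) min(ok) - 1L else grid$range + 1L
    expect_equal(attr(cal, "theta_idx"), brute_theta)
    expect_lte(cal$match_p, pv)
  }
})

test_that("scanning equals brute-force window rescoring on both
           strands", {
  set.seed(33)
  pwm <- calibrate_threshold(random_pwm(4, seed = 77), p_value = 0.02)
  cons <- paste(c("A", "C", "G", "T")[apply(pwm$mat, 1, which.max)],
                collapse = "")
  sv <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  sv[20:23] <- strsplit(cons, "")[[1]]   # guarantee at least one site
  s <- paste(sv, collapse = "")
  got <- scan_promoter(pwm, s)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  pos_b <- integer(0); str_b <- character(0); sc_b <- numeric(0)
  for (pos in 1:(60 - 4 + 1)) {
    win <- sv[pos:(pos + 3)]
    fwd <- sum(vapply(1:4, function(i) pwm$logodds[i, win[i]],
                      numeric(1)))
    bwd <- sum(vapply(1:4, function(i) {
      pwm$logodds[i, rc[win[4 - i + 1]]]
    }, numeric(1)))
    if (fwd >= pwm$threshold) {
      pos_b <- c(pos_b, pos); str_b <- c(str_b, "+")
      sc_b <- c(sc_b, fwd)
    }
    if (bwd >= pwm$threshold) {
      pos_b <- c(pos_b, pos); str_b <- c(str_b, "-")
      sc_b <- c(sc_b, bwd)
    }
  }
  o <- order(pos_b, str_b)
  expect_gt(nrow(got), 0)
  expect_equal(got$position, pos_b[o])
  expect_equal(got$strand, str_b[o])
  expect_equal(got$score, sc_b[o], tolerance = 1e-12)
})

test_that("ambiguous bases, strand symmetry and threshold monotonicity", {
  pwm <- calibrate_threshold(random_pwm(4, seed = 78), p_value = 1e-2)
  cons <- paste(c("A", "C", "G", "T")[apply(pwm$mat, 1, which.max)],
                collapse = "")
  rc_cons <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  pad <- "AAAAAAAAAA"
  expect_gte(nrow(scan_promoter(pwm, paste0(pad, cons, pad))), 1)
  expect_gte(nrow(scan_promoter(pwm, paste0(pad, rc_cons, pad))), 1)
  # N voids every window that covers it
  expect_equal(nrow(scan_promoter(pwm, paste0(substr(cons, 1, 3), "N"))),
               0)
  # reverse-complemented PWM finds the same number of sites
  pwm_rc <- apexatlas:::new_pwm("rc", pwm$mat[4:1, c("T", "G", "C", "A")],
                                background = uniform_bg)
  pwm_rc$threshold <- pwm$threshold
  set.seed(34)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  expect_equal(nrow(scan_promoter(pwm, s)), nrow(scan_promoter(pwm_rc, s)))
  # stricter p-value never adds matches
  tight <- calibrate_threshold(pwm, p_value = 1e-4)
  expect_lte(nrow(scan_promoter(tight, s)), nrow(scan_promoter(pwm, s)))
  expect_gte(tight$threshold, pwm$threshold)
})

test_that("promoter extraction follows the coordinate contract", {
  chrom <- paste(rep("ACGT", 2500), collapse = "")   # 10 kb
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  gm <- data.frame(gene = c("plus", "minus", "edge"),
                   chrom = "chr1", start = c(5000, 3000, 500),
                   end = c(7000, 6000, 1500),
                   strand = c("+", "-", "+"),
                   tss = c(5000, 6000, 500))
  prom <- extract_promoters(gm, genome)
  p <- prom[prom$gene == "plus", ]
  expect_equal(c(p$start, p$end), c(4000, 5499))
  expect_equal(nchar(p$sequence), 1500)
  expect_equal(p$sequence, substr(chrom, 4000, 5499))
  m <- prom[prom$gene == "minus", ]
  expect_equal(c(m$start, m$end), c(5501, 7000))
  expect_equal(m$sequence, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 5501, 7000)))))
  e <- prom[prom$gene == "edge", ]
  expect_true(e$truncated)
  expect_equal(e$start, 1)
  expect_error(extract_promoters(data.frame(gene = "x", chrom = "chr9",
                                            start = 1, end = 2,
                                            strand = "+", tss = 1),
                                 genome), "chr9")
})

test_that("motif enrichment and GRN construction are self-consistent", {
  hits <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                   TRUE, FALSE, TRUE, FALSE), ncol = 2,
                 dimnames = list(sprintf("g%d", 1:4), c("m1", "m2")))
  fams <- c(m1 = "F1", m2 = "F2")
  enr <- motif_enrichment(hits, foreground = c("g1", "g2"),
                          background = sprintf("g%d", 1:4),
                          pwm_families = fams)
  expect_equal(enr$per_pwm$fold[enr$per_pwm$pwm == "m1"],
               (2 / 2) / (2 / 4))
  # uniform hit pattern: fold 1, p 1
  all_hits <- matrix(TRUE, 4, 1, dimnames = list(sprintf("g%d", 1:4),
                                                 "m"))
  e2 <- motif_enrichment(all_hits, c("g1", "g2"), sprintf("g%d", 1:4))
  expect_equal(e2$per_pwm$fold, 1)
  expect_equal(e2$per_pwm$p, 1)
  expect_error(motif_enrichment(hits, "zzz", sprintf("g%d", 1:4)),
               "subset")
  sc <- list(counts = matrix(c(2L, 1L, 0L, 0L, 0L, 3L, 0L, 0L), ncol = 2,
                             dimnames = list(sprintf("g%d", 1:4),
                                             c("m1", "m2"))),
             pwms = list(m1 = list(id = "m1", family = "F1"),
                         m2 = list(id = "m2", family = "F2")))
  sc$hits <- sc$counts > 0
  grn <- build_grn(sc)
  fc <- grn$family_counts
  expect_equal(fc$n_families[fc$gene == "g1"], 1)
  expect_equal(fc$n_families[fc$gene == "g2"], 2)
  expect_equal(fc$n_families[fc$gene == "g4"], 0)
  expect_false("g4" %in% grn$edges$gene)
  # distinct-family counts agree with direct recomputation from hits
  direct <- rowSums(vapply(c("F1", "F2"), function(f) {
    rowSums(sc$hits[, names(sc$pwms)[vapply(sc$pwms, `[[`, "",
                                            "family") == f],
                    drop = FALSE]) > 0
  }, logical(4)))
  expect_equal(fc$n_families, unname(direct))
})
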