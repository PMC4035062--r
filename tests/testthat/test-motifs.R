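test_that("uniform PFM with uniform background scores zero everywhere", {
  pfm <- matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm)
  expect_equal(unname(pwm$scores), matrix(0, 4, 3))
})

test_that("a deterministic column favours its base and penalizes others", {
  pfm <- matrix(c(20, 0, 0, 0), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm)
  expect_gt(pwm$scores["A", 1], 1.9)
  expect_true(all(pwm$scores[c("C", "G", "T"), 1] < 0))
})

test_that("log-odds match a hand-computed two-column example", {
  pfm <- matrix(c(12, 4, 2, 2,
                  0, 0, 18, 2), 4, 2,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm, pseudocount = 0.1)
  # score(A,1) = log2(((12 + 0.1*0.25) / (20 + 0.1)) / 0.25)
  expect_equal(unname(pwm$scores["A", 1]),
               log2(((12 + 0.025) / 20.1) / 0.25), tolerance = 1e-12)
  expect_equal(unname(pwm$scores["G", 2]),
               log2(((18 + 0.025) / 20.1) / 0.25), tolerance = 1e-12)
  expect_error(pfm_to_pwm(matrix(0, 4, 1,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL))), "zero column")
})

test_that("score distribution masses sum to one", {
  motifs <- read_jaspar_pfm(system.file("extdata", "motifs_synthetic.jaspar",
                                        package = "enhancerlink"))
  for (m in motifs[1:4]) {
    dist <- enhancerlink:::.score_distribution(pfm_to_pwm(m))
    expect_equal(sum(dist$mass), 1, tolerance = 1e-9)
  }
})

test_that("width-1 threshold equals direct enumeration over four bases", {
  pfm <- matrix(c(10, 5, 4, 1), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm)
  sc <- sort(round(pwm$scores[, 1] / 0.01))
  # uniform background: each base carries mass 1/4
  tails <- vapply(sc, function(s) mean(round(pwm$scores[, 1] / 0.01) >= s), 1)
  target <- 0.3
  expected <- min(sc[tails <= target]) * 0.01
  expect_equal(score_threshold(pwm, p = target), expected)
})

test_that("DP tail equals brute-force enumeration for short motifs", {
  set.seed(3)
  for (w in c(2, 3, 6)) {
    pfm <- matrix(sample.int(20, 4 * w, replace = TRUE), 4, w,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    pwm <- pfm_to_pwm(pfm, background = bg)
    s_int <- round(pwm$scores / 0.01)
    kmers <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- vapply(seq_len(nrow(kmers)), function(i) {
      sum(s_int[cbind(kmers[i, ], seq_len(w))])
    }, 1)
    probs <- vapply(seq_len(nrow(kmers)), function(i) {
      prod(bg[kmers[i, ]])
    }, 1)
    for (p_target in c(0.2, 0.05, 0.01)) {
      achievable <- sort(unique(scores))
      tails <- vapply(achievable, function(s) sum(probs[scores >= s]), 1)
      idx <- which(tails <= p_target + 1e-12)[1]
      if (is.na(idx)) {
        # even a perfect match is more likely than p_target
        expect_warning(thr <- score_threshold(pwm, p = p_target), "maximum")
        expect_equal(thr, max(achievable) * 0.01, tolerance = 1e-9)
      } else {
        expect_equal(score_threshold(pwm, p = p_target),
                     achievable[idx] * 0.01, tolerance = 1e-9)
      }
    }
  }
})

test_that("threshold is monotone in the target p-value", {
  pwm <- pfm_to_pwm(consensus_pfm("TGACTCA"))
  t1 <- score_threshold(pwm, p = 1e-2)
  t2 <- score_threshold(pwm, p = 1e-3)
  t3 <- score_threshold(pwm, p = 1e-4)
  expect_true(t1 <= t2 && t2 <= t3)
})

test_that("consensus and its reverse complement are both hits", {
  pwm <- pfm_to_pwm(consensus_pfm("TGACTCA"))
  thr <- score_threshold(pwm, p = 1e-4)
  pad <- function(x) paste0("AACCGGAACC", x, "AACCGGAACC")
  seqs <- c(fwd = pad("TGACTCA"), rev = pad("TGAGTCA"),
            none = pad("AAAAAAA"), enn = pad("TGANTCA"))
  res <- scan_regions(seqs, pwm, thr)
  expect_true(res$region_hit[["fwd"]])
  expect_true(res$region_hit[["rev"]])
  expect_false(res$region_hit[["none"]])
  expect_false(res$region_hit[["enn"]])  # N windows are skipped
  expect_true(all(res$hits$strand[res$hits$region == "rev"] == "-"))
})

test_that("regions shorter than the motif are reported unhit with warning", {
  pwm <- pfm_to_pwm(consensus_pfm("TGACTCA"))
  expect_warning(res <- scan_regions(c(short = "ACGT"), pwm, 5), "shorter")
  expect_false(res$region_hit[["short"]])
})

test_that("scan hits match a naive per-window rescan", {
  set.seed(8)
  pwm <- pfm_to_pwm(consensus_pfm("TGTTTAC", strength = 12))
  thr <- score_threshold(pwm, p = 1e-3)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:100, function(i) {
    paste(sample(bases, 60, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- sprintf("r%03d", 1:100)
  res <- scan_regions(seqs, pwm, thr)
  # naive oracle: explicit window loop on both strands
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  s_int <- round(pwm$scores / 0.01)
  score1 <- function(win) {
    idx <- match(strsplit(win, "")[[1]], bases)
    sum(s_int[cbind(idx, seq_along(idx))])
  }
  naive <- vapply(seqs, function(s) {
    w <- ncol(pwm$scores)
    wins <- vapply(1:(nchar(s) - w + 1), function(i) {
      substr(s, i, i + w - 1)
    }, "")
    any(vapply(wins, function(x) {
      score1(x) >= round(thr / 0.01) || score1(rc(x)) >= round(thr / 0.01)
    }, TRUE))
  }, TRUE)
  expect_equal(unname(res$region_hit), unname(naive))
})

test_that("enrichment table reproduces the published FOS row", {
  tab <- enrichment_table(c(FOS = 398), 1004, c(FOS = 650), 1047)
  expect_equal(unname(signif(tab$p_value, 2)), 2.9e-24)
  expect_equal(tab$count_a, 398L)
  expect_equal(tab$count_b, 650L)
})

test_that("equal proportions are excluded and rows sort by p", {
  tab <- enrichment_table(c(null = 100, strong = 300, weak = 140),
                          1000,
                          c(null = 100, strong = 100, weak = 100),
                          1000)
  expect_false("null" %in% tab$motif)
  expect_equal(tab$motif, c("strong", "weak"))
  expect_true(all(diff(tab$p_value) >= 0))
  expect_error(enrichment_table(c(x = 1), 0, c(x = 1), 10), "positive")
  expect_error(enrichment_table(c(x = 11), 10, c(x = 1), 10), "exceed")
})

test_that("the planted motif ranks first against decoys", {
  ds <- small_dataset()
  motifs <- read_jaspar_pfm(system.file("extdata", "motifs_synthetic.jaspar",
                                        package = "enhancerlink"))
  spec <- ds$enhancers[ds$enhancers$cell %in% c("A", "B"), ]
  seq_a <- ds$sequences[spec$name[spec$cell == "A"]]
  seq_b <- ds$sequences[spec$name[spec$cell == "B"]]
  hits_a <- hits_b <- integer(0)
  pwms <- lapply(motifs, pfm_to_pwm)
  for (m in names(pwms)) {
    # short decoys cannot reach 1e-4 and fall back to their maximum score
    thr <- suppressWarnings(score_threshold(pwms[[m]], p = 1e-4))
    hits_a[m] <- sum(scan_regions(seq_a, pwms[[m]], thr)$region_hit)
    hits_b[m] <- sum(scan_regions(seq_b, pwms[[m]], thr)$region_hit)
  }
  tab <- enrichment_table(hits_a, length(seq_a), hits_b, length(seq_b),
                          motifs = pwms)
  expect_equal(tab$motif[1], "AP1_syn")  # the planted TGACTCA motif
  expect_equal(unname(tab$database[1]), "JASPAR")
})

test_that("JASPAR and MEME readers agree on a shared motif", {
  motifs <- read_jaspar_pfm(system.file("extdata", "motifs_synthetic.jaspar",
                                        package = "enhancerlink"))
  expect_length(motifs, 8)
  expect_true(all(vapply(motifs, nrow, 1L) == 4))
  ap1 <- motifs$AP1_syn
  meme_path <- withr::local_tempfile(fileext = ".meme")
  probs <- t(sweep(ap1, 2, colSums(ap1), "/"))
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF AP1_syn", "",
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20",
            ncol(ap1)),
    apply(probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  ), meme_path)
  back <- read_meme_pfm(meme_path)
  expect_equal(as.vector(back$AP1_syn), as.vector(ap1), tolerance = 1e-4)
})
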