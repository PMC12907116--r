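# PWM construction, scanning, enrichment, profiles and TF nomination.

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# a sharply informative test motif (consensus TACGGTCA)
sharp_motif <- function(name = "M1") {
  cons <- c("T", "A", "C", "G", "G", "T", "C", "A")
  pfm <- matrix(0, 4, length(cons), dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(cons)) pfm[cons[j], j] <- 20
  motif_model(name, pfm)
}

test_that("pfm_to_pwm reproduces the worked log-odds arithmetic", {
  pfm <- matrix(c(9, 1, 2, 3,
                  5, 5, 5, 5,
                  0, 0, 15, 0,
                  2, 2, 2, 9), 4,
                dimnames = list(c("A", "C", "G", "T")))
  m <- motif_model("w", pfm)
  pwm <- pfm_to_pwm(m)
  # column 1: colsum = 15 + 1 = 16; freq_A = 9.25/16; ratio = 2.3125
  expect_equal(unname(pwm["A", 1]), log2(2.3125), tolerance = 1e-12)
  expect_equal(unname(pwm["C", 1]), log2((1.25 / 16) / 0.25),
               tolerance = 1e-12)
  # uniform column scores 0 for every base
  expect_equal(unname(pwm[, 2]), rep(0, 4))
  # dominant base in a 15/0.25 column
  expect_equal(unname(pwm["G", 3]), log2((15.25 / 16) / 0.25),
               tolerance = 1e-12)
  expect_equal(pwm_max_score(pwm),
               sum(apply(pwm, 2, max)))
  expect_equal(m$consensus, "AAGT")
})

test_that("motif_model validates its inputs", {
  pfm <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T")))
  expect_error(motif_model("x", pfm[, 1:3]), "width")
  expect_error(motif_model("x", -pfm), "negative")
  expect_error(motif_model("x", pfm, background = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
})

test_that("scanning finds a planted consensus at the right offset", {
  m <- sharp_motif()
  pwm <- pfm_to_pwm(m)
  set.seed(301)
  left <- rand_seq(40); right <- rand_seq(30)
  seq <- paste0(left, m$consensus, right)
  hits <- scan_sequence(seq, pwm)
  fwd <- hits[hits$strand == "+", ]
  expect_true(40 %in% fwd$offset)
  best <- fwd[fwd$offset == 40, ]
  expect_equal(best$score, pwm_max_score(pwm), tolerance = 1e-10)

  # the same site is found on the reverse strand of the RC sequence,
  # with the offset mapped back to forward coordinates
  hits_rc <- scan_sequence(revcomp(seq), pwm)
  L <- nchar(seq)
  mapped <- L - m$width - hits_rc$offset
  expect_true(40 %in% mapped[hits_rc$strand == "-"])
})

test_that("both-strand scanning is symmetric under reverse complement", {
  m <- sharp_motif()
  pwm <- pfm_to_pwm(m)
  set.seed(302)
  for (i in 1:10) {
    seq <- rand_seq(150)
    # lower the threshold so random hits occur
    a <- scan_sequence(seq, pwm, min_score = 0.3 * pwm_max_score(pwm))
    b <- scan_sequence(revcomp(seq), pwm,
                       min_score = 0.3 * pwm_max_score(pwm))
    # every forward hit in a corresponds to a reverse hit in b and
    # vice versa, with identical scores
    L <- nchar(seq); w <- m$width
    key <- function(h) {
      flip <- ifelse(h$strand == "+", "-", "+")
      paste(L - w - h$offset, flip, round(h$score, 8))
    }
    expect_setequal(key(a), paste(b$offset, b$strand, round(b$score, 8)))
  }
})

test_that("forward-strand hits agree with Biostrings matchPWM", {
  m <- sharp_motif()
  pwm <- pfm_to_pwm(m)
  thr <- 0.6 * pwm_max_score(pwm)
  set.seed(303)
  for (i in 1:5) {
    seq <- paste0(rand_seq(60), m$consensus, rand_seq(60))
    mine <- scan_sequence(seq, pwm, min_score = thr)
    fwd <- sort(mine$offset[mine$strand == "+"]) + 1L  # 1-based
    ref <- Biostrings::matchPWM(pwm, Biostrings::DNAString(seq),
                                min.score = thr)
    expect_equal(fwd, sort(BiocGenerics::start(ref)))
  }
})

test_that("scan_peaks returns per-peak hits and an empty frame when none", {
  m <- sharp_motif()
  seqs <- c(p1 = paste0(strrep("C", 30), m$consensus, strrep("C", 30)),
            p2 = strrep("C", 68))
  hits <- scan_peaks(seqs, m)
  expect_equal(unique(hits$peak_id), "p1")
  expect_equal(hits$offset[1], 30)
  none <- scan_peaks(c(p2 = strrep("C", 68)), m)
  expect_equal(nrow(none), 0)
  # DNAStringSet input is equivalent
  dss <- Biostrings::DNAStringSet(seqs)
  expect_equal(scan_peaks(dss, m), hits)
})

test_that("motif enrichment reproduces exact hypergeometric tail values", {
  m <- sharp_motif()
  with_m <- function(id) setNames(
    paste0(strrep("C", 46), m$consensus, strrep("C", 47)), id)
  without <- function(id) setNames(strrep("C", 101), id)
  fg <- paste0("f", 1:5); bg <- paste0("b", 1:5)
  seqs <- c(unlist(lapply(fg, with_m)), unlist(lapply(bg, without)))
  res <- motif_enrichment(fg, bg, seqs, m)
  expect_equal(res$fg_with_motif, 5)
  expect_equal(res$bg_with_motif, 0)
  # all 5 carriers drawn into a foreground of 5 out of 10: p = 1/C(10,5)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$padj, res$p)

  # equal carriage rates are not enriched
  seqs2 <- c(with_m("f1"), without("f2"), with_m("b1"), without("b2"))
  res2 <- motif_enrichment(c("f1", "f2"), c("b1", "b2"), seqs2, m)
  expect_gt(res2$p, 0.5)

  # motif only in the background: fold 0, p = 1
  seqs3 <- c(without("f1"), without("f2"), with_m("b1"), with_m("b2"))
  res3 <- motif_enrichment(c("f1", "f2"), c("b1", "b2"), seqs3, m)
  expect_equal(res3$fold, 0)
  expect_equal(res3$p, 1)

  expect_error(motif_enrichment(character(), bg, seqs, m), "empty")
  expect_error(motif_enrichment(fg, fg, seqs, m), "disjoint")
  expect_error(motif_enrichment(c(fg, "nope"), bg, seqs, m), "nope")
})

test_that("the summit window excludes distal hits from enrichment", {
  m <- sharp_motif()
  # motif centered 300 bp from the summit (summit at midpoint 350 of 701)
  far <- setNames(paste0(strrep("C", 46), m$consensus, strrep("C", 647)),
                  "f1")
  near <- setNames(paste0(strrep("C", 346), m$consensus, strrep("C", 347)),
                   "f2")
  bg <- setNames(strrep("C", 701), "b1")
  res <- motif_enrichment(c("f1", "f2"), "b1", c(far, near, bg), m,
                          window = 200)
  expect_equal(res$fg_with_motif, 1)  # only the near hit counts
  wide <- motif_enrichment(c("f1", "f2"), "b1", c(far, near, bg), m,
                           window = 400)
  expect_equal(wide$fg_with_motif, 2)
})

test_that("occurrence profile places hits in the right summit-relative bin", {
  m <- sharp_motif()
  # hit centers at -500 (first bin), -1 (bin 50), 0 (bin 51), +495 (last)
  w <- m$width
  hits <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4"),
    offset = c(100 - 500, 100 - 1, 100, 100 + 495) - floor(w / 2),
    strand = "+", score = 10)
  so <- setNames(rep(100L, 4), hits$peak_id)
  prof <- occurrence_profile(hits, w, so, n_peaks = 8)
  expect_equal(nrow(prof), 100)
  expect_equal(prof$occurrence[1], 1 / 8)
  expect_equal(prof$occurrence[50], 1 / 8)
  expect_equal(prof$occurrence[51], 1 / 8)
  expect_equal(prof$occurrence[100], 1 / 8)
  expect_equal(sum(prof$occurrence), 4 / 8)
  # two hits in one peak in the same bin count once
  hits2 <- rbind(hits, data.frame(peak_id = "p3", offset = hits$offset[3] + 2,
                                  strand = "-", score = 9))
  prof2 <- occurrence_profile(hits2, w, so, n_peaks = 8)
  expect_equal(prof2$occurrence[51], 1 / 8)
})

test_that("footprint depth is flank mean minus core mean", {
  m <- sharp_motif()
  w <- m$width
  # flat insertion rate 4 with a core dip to 1
  v <- rep(4, 200)
  v[81:(80 + w)] <- 1
  ins <- list(pk = v)
  hits <- data.frame(peak_id = "pk", offset = 80L, strand = "+", score = 10)
  fp <- footprint_profile(ins, hits, w, flank = 50)
  expect_equal(fp$n_hits, 1L)
  expect_length(fp$profile, w + 100)
  expect_equal(fp$depth, 3)
  # hits whose flanks fall off the vector are skipped
  edge <- data.frame(peak_id = "pk", offset = 10L, strand = "+", score = 10)
  expect_equal(footprint_profile(ins, edge, w)$n_hits, 0L)
  expect_true(is.na(footprint_profile(ins, edge, w)$depth))
})

test_that("TF nomination requires both the motif and the expression gate", {
  enr <- function(tfs, padj) data.frame(tf = tfs, fg_with_motif = 5,
                                        fg_total = 10, bg_with_motif = 1,
                                        bg_total = 50, fold = 25,
                                        p = padj, padj = padj)
  de <- function(genes, calls) data.frame(feature_id = genes, call = calls,
                                          log2fc = 1)
  map <- data.frame(tf = c("TFA", "TFB"), gene_id = c("gA", "gB"))
  ebs <- list(
    all = list(opening = enr(c("TFA", "TFB"), c(0.001, 0.001)),
               closing = NULL),
    female = list(opening = enr("TFA", 0.01), closing = NULL))
  dbs <- list(all = de(c("gA", "gB"), c("up", "ns")),
              female = de(c("gA", "gB"), c("up", "up")))
  nom <- nominate_tfs(ebs, dbs, map)
  # TFB is enriched but not expressed up in "all" and not enriched in
  # "female", so only TFA is nominated, with both strata as support
  expect_equal(nom$tf, "TFA")
  expect_equal(nom$direction, "opening+up")
  expect_equal(nom$stratum_support, "all,female")
  expect_equal(nom$n_strata, 2L)

  # non-significant enrichment blocks nomination
  ebs2 <- list(all = list(opening = enr("TFA", 0.2), closing = NULL))
  expect_equal(nrow(nominate_tfs(ebs2, dbs["all"], map)), 0)

  # closing+down mirrors
  ebs3 <- list(all = list(opening = NULL, closing = enr("TFA", 0.01)))
  dbs3 <- list(all = de("gA", "down"))
  nom3 <- nominate_tfs(ebs3, dbs3, map)
  expect_equal(nom3$direction, "closing+down")

  # unknown TF and missing gene raise warnings and are skipped
  ebs4 <- list(all = list(opening = enr("TFZ", 0.001), closing = NULL))
  expect_warning(n4 <- nominate_tfs(ebs4, dbs["all"], map), "tf_gene_map")
  expect_equal(nrow(n4), 0)
  ebs5 <- list(all = list(opening = enr("TFA", 0.001), closing = NULL))
  dbs5 <- list(all = de("gOther", "up"))
  expect_warning(n5 <- nominate_tfs(ebs5, dbs5, map), "absent")
  expect_equal(nrow(n5), 0)
})

test_that("TF target assignment joins motif peaks to nearest genes", {
  pks <- gr("chr1", c(1000, 8000, 30000), c(1400, 8400, 30400),
            name = c("pA", "pB", "pC"))
  hits <- data.frame(peak_id = c("pA", "pC"), offset = 10L,
                     strand = "+", score = 9)
  tss <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1500, 31000), width = 1),
                                strand = "+", gene_id = c("g1", "g2"))
  de <- data.frame(feature_id = c("g1", "g2"),
                   call = c("up", "ns"), log2fc = c(2.1, 0.1))
  tg <- assign_tf_targets(pks, hits, tss, de)
  # pB has no motif hit and is excluded
  expect_setequal(tg$peak_id, c("pA", "pC"))
  expect_equal(tg$gene_id[tg$peak_id == "pA"], "g1")
  expect_equal(tg$de_call[tg$peak_id == "pA"], "up")
  expect_equal(tg$gene_log2fc[tg$peak_id == "pC"], 0.1)
  # no motif-bearing peaks: empty frame with the right columns
  empty <- assign_tf_targets(pks, hits[0, ], tss, de)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("gene_id", "peak_id", "de_call", "gene_log2fc"))
})

test_that("PFM files round-trip through the JASPAR reader/writer", {
  m <- sharp_motif("RTRIP")
  f <- tempfile(fileext = ".pfm")
  write_jaspar_pfm(m, f)
  back <- read_jaspar_pfm(f)
  expect_length(back, 1)
  expect_equal(back[[1]]$name, "RTRIP")
  expect_equal(unname(back[[1]]$pfm), unname(m$pfm))
  expect_equal(back[[1]]$consensus, m$consensus)
})
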