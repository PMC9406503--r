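# PAS and ARE scanners on transcribed variants.

test_that("the PAS scanner reports all overlapping AATAAA occurrences", {
  h <- scan_pas("AATAAA", "v")
  expect_identical(h$start, 1L)
  expect_identical(h$end, 6L)
  expect_identical(h$matched, "AATAAA")
  expect_identical(nrow(scan_pas("CCCCCC")), 0L)
  # two overlapping copies
  h2 <- scan_pas("AATAAATAAA")
  expect_identical(h2$start, c(1L, 5L))
  expect_identical(h2$matched, rep("AATAAA", 2L))
  # N is literal: it never completes a motif
  expect_identical(nrow(scan_pas("AATAAN")), 0L)
})

test_that("ARE class I reports each pentamer, class II merges overlapping runs", {
  h1 <- scan_are("ATTTA", "ARE_I")
  expect_identical(h1[, c("start", "end", "matched")],
                   data.frame(start = 1L, end = 5L, matched = "ATTTA"))
  # two overlapping copies: class I reports both, class II one merged span
  expect_identical(scan_are("ATTTATTTA", "ARE_I")$start, c(1L, 5L))
  h2 <- scan_are("ATTTATTTA", "ARE_II")
  expect_identical(h2[, c("start", "end", "matched")],
                   data.frame(start = 1L, end = 9L, matched = "ATTTATTTA"))
  # three copies still one run; separated copies are not class II
  h3 <- scan_are("ATTTATTTATTTA", "ARE_II")
  expect_identical(h3$end - h3$start + 1L, 13L)
  expect_identical(nrow(scan_are("ATTTAGGGGATTTA", "ARE_II")), 0L)
})

test_that("ARE class III reports the literal TTTC and merged T-rich regions", {
  lit <- scan_are("GGTTTCGG", "ARE_III")
  expect_identical(lit[, c("start", "end", "matched")],
                   data.frame(start = 3L, end = 6L, matched = "TTTC"))
  rich <- scan_are("TTTTTTTT", "ARE_III", w = 8, t_frac = 0.75)
  win <- rich[rich$matched != "TTTC", ]
  expect_identical(nrow(win), 1L)
  expect_identical(c(win$start, win$end), c(1L, 8L))
  # windows qualify at threshold exactly (6 T in 8), and merged regions span
  # every qualifying window
  rich2 <- scan_are("GGTTTTTTTTGG", "ARE_III", w = 8, t_frac = 0.75)
  win2 <- rich2[rich2$matched != "TTTC", ]
  expect_identical(c(win2$start, win2$end), c(1L, 12L))

  expect_error(scan_are("ACGT", "ARE_III", w = 3), "w")
  expect_error(scan_are("ACGT", "ARE_III", t_frac = 0), "t_frac")
  expect_error(scan_are("ACGT", "ARE_III", t_frac = 1.5), "t_frac")
})

test_that("every reported hit re-checks under naive scanners", {
  set.seed(11L)
  for (i in 1:20) {
    # T/A-rich background so motifs actually occur
    seq <- paste(sample(c("A", "T", "T", "C", "G"), 120, replace = TRUE),
                 collapse = "")
    pas <- scan_pas(seq)
    expect_identical(pas$start, naive_occurrences(seq, "AATAAA"))
    are1 <- scan_are(seq, "ARE_I")
    expect_identical(are1$start, naive_occurrences(seq, "ATTTA"))
    for (k in seq_len(nrow(are1))) {
      expect_identical(substr(seq, are1$start[k], are1$end[k]), "ATTTA")
    }
    are3 <- scan_are(seq, "ARE_III", w = 8, t_frac = 0.75)
    lit <- are3[are3$matched == "TTTC", ]
    expect_identical(lit$start, naive_occurrences(seq, "TTTC"))
    win <- are3[are3$matched != "TTTC", ]
    naive <- naive_t_rich(seq, 8L, 0.75)
    expect_identical(win$start, naive$start)
    expect_identical(win$end, naive$end)
    # every hit's matched text is the substring it claims to be
    all_hits <- rbind(pas, are1, are3)
    for (k in seq_len(nrow(all_hits))) {
      expect_identical(all_hits$matched[k],
                       substr(seq, all_hits$start[k], all_hits$end[k]))
    }
  }
})

test_that("motif scanning is literal: no implicit complementing on reversal", {
  fwd <- "AAATAA"                      # no PAS as written
  rev_ <- paste(rev(strsplit(fwd, "")[[1L]]), collapse = "")  # "AATAAA"
  expect_identical(nrow(scan_pas(fwd)), 0L)
  expect_identical(nrow(scan_pas(rev_)), 1L)
  # the reverse complement would NOT contain the motif; reversal does
  expect_identical(nrow(scan_pas(revcomp(fwd))), 0L)
})

test_that("scan_motifs aggregates classes across a variant table", {
  v <- enumerate_variants(example_peptides()[["abeta42"]], "abeta42")
  m <- scan_motifs(v)
  expect_true(all(m$motif_class %in% c("PAS", "ARE_I", "ARE_II", "ARE_III")))
  expect_true(all(m$variant_id %in% v$variant_id))
  # forward variants carry both a PAS and a literal TTTC
  fwd <- m[m$variant_id == "abeta42|fwd|S-C", ]
  expect_true(any(fwd$motif_class == "PAS"))
  expect_true(any(fwd$matched == "TTTC"))
  expect_identical(nrow(scan_motifs(v[0, ])), 0L)
})
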