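test_that("assembly concatenates copies in order with spacers", {
  reg <- data.frame(name = c("A", "B"),
                    sequence = c("ACGT", "TTAA"))
  one <- assemble_promoter(reg, order = "A", copies = 1)
  expect_equal(one$sequence, "ACGT")
  expect_equal(one$features$start, 0)
  expect_equal(one$features$end, 4)

  two <- assemble_promoter(reg, order = c("A", "B"), copies = 2,
                           spacer = "GG")
  expect_equal(two$sequence, "ACGTGGACGTGGTTAAGGTTAA")
  expect_equal(two$length, 22)
  expect_equal(two$features$name, c("A", "A", "B", "B"))

  expect_error(assemble_promoter(reg, order = "C"), "unknown motif")
})

test_that("the default D5 layout has 3 copies each in block order", {
  d5 <- assemble_promoter(default_motif_registry())
  expect_equal(d5$features$name, rep(c("NFKB", "CRE", "HRE"), each = 3))
  expect_equal(nrow(d5$features), 9)
  expect_equal(d5$length, 3 * 10 + 3 * 8 + 3 * 5)
})

test_that("length conservation and copy exactness hold for random layouts", {
  set.seed(61)
  bases <- c("A", "C", "G", "T")
  for (i in 1:20) {
    n_motifs <- sample(1:4, 1)
    reg <- data.frame(
      name = paste0("M", seq_len(n_motifs)),
      sequence = vapply(seq_len(n_motifs), function(j) {
        paste(sample(bases, sample(4:12, 1), replace = TRUE),
              collapse = "")
      }, character(1)))
    copies <- sample(1:4, n_motifs, replace = TRUE)
    spacer <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                    collapse = "")
    pc <- assemble_promoter(reg, reg$name, copies, spacer)
    n_el <- sum(copies)
    expect_equal(pc$length,
                 sum(nchar(reg$sequence) * copies) +
                   nchar(spacer) * (n_el - 1))
    # each feature slices out exactly its motif sequence
    for (r in seq_len(nrow(pc$features))) {
      f <- pc$features[r, ]
      motif <- reg$sequence[match(f$name, reg$name)]
      expect_equal(substr(pc$sequence, f$start + 1, f$end), motif)
    }
    counts <- table(pc$features$name)
    expect_equal(unname(counts[reg$name]), copies, ignore_attr = TRUE)
    # features are sorted and non-overlapping
    expect_true(all(diff(pc$features$start) > 0))
    expect_true(all(pc$features$start[-1] >=
                      head(pc$features$end, -1)))
  }
})

test_that("degenerate IUPAC motifs need a declared matching expansion", {
  reg <- data.frame(name = "HREc", sequence = "RCGTG")
  expect_error(assemble_promoter(reg, "HREc"), "expansion")
  reg$expansion <- "ACGTG"
  ok <- assemble_promoter(reg, "HREc", copies = 2)
  expect_equal(ok$sequence, "ACGTGACGTG")
  reg$expansion <- "TCGTG"  # T does not match R = A/G
  expect_error(assemble_promoter(reg, "HREc"), "does not match")
})

test_that("restriction scanning reports both strands at forward offsets", {
  kpn <- default_enzymes()$KpnI
  hits <- scan_restriction_sites("AAAGGTACCTGA", list(kpn))
  expect_equal(hits$offset, 3)
  expect_equal(hits$enzyme, "KpnI")

  # the KpnI-tailed forward primer contains its own site
  primer <- "AAAGGTACCTGAACTTTCTGCTGTCTTGGG"
  expect_equal(nrow(scan_restriction_sites(primer, list(kpn))), 1)

  expect_equal(nrow(scan_restriction_sites("AAAA", list(kpn))), 0)
  expect_equal(nrow(scan_restriction_sites("", list(kpn))), 0)

  # non-palindromic site: a reverse-complement occurrence is reported
  bsai <- restriction_enzyme("BsaI", "GGTCTC")
  rc_hit <- scan_restriction_sites("TTGAGACCTT", list(bsai))
  expect_equal(rc_hit$offset, 2)
  # palindromic sites are reported once per position
  mlu <- default_enzymes()$MluI
  expect_equal(nrow(scan_restriction_sites("AAACGCGTAA", list(mlu))), 1)
})

test_that("the default construct is clone-safe for the four enzymes", {
  d5 <- assemble_promoter(default_motif_registry())
  expect_equal(nrow(scan_restriction_sites(d5$sequence,
                                           default_enzymes())), 0)
})

test_that("primer construction follows prefix + site + anneal structure", {
  enz <- default_enzymes()
  target <- "TGAACTTTCTGCTGTCTTGGG"
  pr <- design_primers(target, enz$KpnI, enz$BglII, prefix = "AAA",
                       anneal_length = 21)
  expect_equal(pr$forward, "AAAGGTACCTGAACTTTCTGCTGTCTTGGG")

  # palindromic toy: forward and reverse coincide
  eco <- restriction_enzyme("EcoRI", "GAATTC")
  toy <- design_primers("ACGT", eco, eco, prefix = "", anneal_length = 4)
  expect_equal(toy$forward, "GAATTCACGT")
  expect_equal(toy$reverse, "GAATTCACGT")

  # hand-computed reverse primer
  rv <- design_primers("ATGCCC", eco, enz$BglII, prefix = "AAA",
                       anneal_length = 3)
  expect_equal(rv$reverse, "AAAAGATCTGGG")

  expect_error(design_primers("ACGT", eco, eco, anneal_length = 5),
               "anneal_length")

  # internal site triggers a warning entry
  warned <- design_primers("AAGGTACCAA", enz$KpnI, enz$BglII,
                           anneal_length = 4)
  expect_match(warned$warnings, "KpnI")
})

test_that("stripping tails from primers recovers the target ends", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  enz <- default_enzymes()
  for (i in 1:10) {
    target <- paste(sample(bases, sample(25:60, 1), replace = TRUE),
                    collapse = "")
    anneal <- sample(10:20, 1)
    pr <- design_primers(target, enz$KpnI, enz$BglII, prefix = "AAA",
                         anneal_length = anneal)
    fw_core <- sub("^AAAGGTACC", "", pr$forward)
    expect_equal(fw_core, substr(target, 1, anneal))
    rv_core <- sub("^AAAAGATCT", "", pr$reverse)
    expect_equal(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rv_core))),
      substr(target, nchar(target) - anneal + 1, nchar(target)))
  }
})

test_that("construct files round-trip and wrap FASTA at 60 columns", {
  dir <- withr::local_tempdir()
  reg <- data.frame(name = "M", sequence = strrep("ACGTA", 13))  # 65 bp
  pc <- assemble_promoter(reg, "M", copies = 2)  # 130 bp
  paths <- write_construct(pc, file.path(dir, "c130"))
  lines <- readLines(paths[["fasta"]])
  expect_equal(nchar(lines[-1]), c(60, 60, 10))

  back <- read_construct(file.path(dir, "c130"))
  expect_equal(back$sequence, pc$sequence)
  expect_equal(back$features, pc$features)

  tiny <- assemble_promoter(data.frame(name = "T", sequence = "ACGT"),
                            "T", 1)
  write_construct(tiny, file.path(dir, "tiny"))
  body <- readLines(file.path(dir, "tiny.fasta"))[-1]
  expect_equal(body, "ACGT")
})
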