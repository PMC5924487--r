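test_that("quantile normalization equalizes column distributions", {
  # hand-computed rank means: columns (1,5) and (3,7) both become (2,6)
  co <- manual_cohort(matrix(c(1, 5, 3, 7), nrow = 2),
                      c("tumor", "normal"))
  norm <- quantile_normalize(co)
  expect_equal(unname(norm$values), matrix(c(2, 6, 2, 6), nrow = 2))

  # identical columns are a fixed point
  same <- manual_cohort(matrix(c(4, 2, 9, 4, 2, 9), nrow = 3),
                        c("tumor", "normal"))
  expect_equal(quantile_normalize(same)$values, same$values)

  # after normalization all sorted columns agree
  cfg <- small_config()
  norm <- quantile_normalize(generate_cohort(cfg))
  sorted <- apply(norm$values, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1L]) < 1e-12))

  bad <- manual_cohort(matrix(c(1, 2, 3, 4), nrow = 2),
                       c("tumor", "normal"))
  bad$values[1L, 1L] <- NA
  expect_error(quantile_normalize(bad), "missing")
})

test_that("fold changes follow the tumor-minus-normal arithmetic", {
  # equal arms give zero
  null_fc <- manual_fc(matrix(5, 3, 4), matrix(5, 3, 4))
  expect_equal(null_fc$fc, rep(0, 3))

  # tumor mean 6 vs normal mean 4 gives 2
  fc <- manual_fc(matrix(6, 2, 3), matrix(4, 2, 3))
  expect_equal(fc$fc, rep(2, 2))
  expect_equal(fc$n_tumor, rep(3L, 2))

  # three datasets with per-dataset fc 0.5/1.2/1.4: median is 1.2
  blocks <- lapply(c(0.5, 1.2, 1.4), function(d) {
    vals <- cbind(matrix(d, 1, 2), matrix(0, 1, 2))
    colnames(vals) <- paste0("S", d * 10, c("a", "b", "c", "d"))
    rownames(vals) <- "G001"
    list(values = vals,
         meta = data.frame(sample_id = colnames(vals),
                           condition = c("tumor", "tumor",
                                         "normal", "normal"),
                           cancer_type = "CT01",
                           dataset_id = paste0("DS", d * 10)))
  })
  cohort <- expr_cohort(do.call(cbind, lapply(blocks, `[[`, "values")),
                        do.call(rbind, lapply(blocks, `[[`, "meta")))
  expect_equal(log2_fold_change(cohort, "CT01", "median")$fc, 1.2)
  expect_equal(log2_fold_change(cohort, "CT01", "mean")$fc,
               mean(c(0.5, 1.2, 1.4)))
  expect_equal(log2_fold_change(cohort, "CT01", "any-dataset")$fc, 1.4)

  expect_error(log2_fold_change(cohort, "CT99"), "CT99")
})

test_that("relabeling tumor and normal negates every fold change", {
  cfg <- small_config(seed = 3)
  co <- generate_cohort(cfg)
  swapped <- expr_cohort(co$values, within(co$sample_meta, {
    condition <- ifelse(condition == "tumor", "normal", "tumor")
  }))
  for (agg in c("median", "mean")) {
    a <- log2_fold_change(co, "CT01", agg)
    b <- log2_fold_change(swapped, "CT01", agg)
    expect_equal(b$fc, -a$fc)
  }
})

test_that("a dataset missing an arm is reported by name", {
  vals <- matrix(1, 2, 4,
                 dimnames = list(c("G1", "G2"), paste0("S", 1:4)))
  meta <- data.frame(sample_id = paste0("S", 1:4),
                     condition = c("tumor", "normal", "tumor", "normal"),
                     cancer_type = "CT01",
                     dataset_id = c("DS1", "DS1", "DS2", "DS2"))
  expect_error(expr_cohort(vals, within(meta, {
    condition[3:4] <- "tumor"
  })), "DS2")
})

test_that("the selection funnel applies TF, GO and FC filters jointly", {
  # 5 genes: 3 TFs, 2 of them GO-annotated, 1 of those passes FC
  tumor <- matrix(c(1.5, 0.2, 2.0, 3.0, 0.1), 5, 4)
  fc <- manual_fc(tumor, matrix(0, 5, 4))
  genes <- fc$gene  # G001..G005
  sets <- list("GO:0016049" = genes[1:2], "GO:0001525" = character(0))
  cand <- select_tfs(fc, tf_catalog = genes[c(1, 2, 5)],
                     gene_sets = sets)
  expect_equal(cand$gene[cand$selected], genes[1])
  expect_equal(cand$is_tf, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(cand$go_growth, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cand$passes_fc, c(TRUE, FALSE, TRUE, TRUE, FALSE))

  # funnel stages are nested
  f <- attr(cand, "funnel")
  expect_lte(f$n_selected, f$n_pass_fc)
  expect_lte(f$n_pass_fc, f$n_go_unique)
  expect_lte(f$n_go_unique, f$n_tf)
  expect_lte(f$n_go_unique, f$n_go_with_multiplicity)

  # empty catalog empties the funnel
  none <- select_tfs(fc, character(0), sets)
  expect_equal(sum(none$selected), 0)

  expect_error(select_tfs(fc, genes, list(foo = genes)), "GO:0016049")
})

test_that("the fold-change boundary follows the >= convention", {
  fc <- manual_fc(matrix(1, 1, 3), matrix(0, 1, 3))
  sets <- list("GO:0016049" = "G001", "GO:0001525" = character(0))
  at <- select_tfs(fc, "G001", sets, selection_config(fc_threshold = 1))
  expect_true(at$selected)
  strict <- select_tfs(fc, "G001", sets,
                       selection_config(fc_threshold = 1, strict = TRUE))
  expect_false(strict$selected)
})

test_that("overexpression fractions count tumor samples above cutoff", {
  # all tumor samples at the normal mean: fraction 0
  co <- manual_cohort(matrix(3, 1, 8),
                      rep(c("tumor", "normal"), each = 4))
  expect_equal(overexpression_fraction(co, "G001", "CT01"), 0)

  # all tumor samples at normal mean + 2 with margin 1: fraction 1
  vals <- matrix(c(rep(5, 4), rep(3, 4)), 1)
  co <- manual_cohort(vals, rep(c("tumor", "normal"), each = 4))
  expect_equal(overexpression_fraction(co, "G001", "CT01", margin = 1), 1)

  # 3 of 10 tumor samples above cutoff: 0.3
  vals <- matrix(c(rep(4.5, 3), rep(3.2, 7), rep(3, 5)), 1)
  co <- manual_cohort(vals, rep(c("tumor", "normal"), c(10, 5)))
  expect_equal(overexpression_fraction(co, "G001", "CT01", margin = 1),
               0.3)
  expect_error(overexpression_fraction(co, "NOPE", "CT01"), "NOPE")
})

test_that("co-expression counts genes per sample and is monotone", {
  # one tumor sample overexpressing exactly 2 of 3 genes
  vals <- matrix(c(5, 5, 3, 3, 3, 3), 3,
                 dimnames = list(c("G001", "G002", "G003"), NULL))
  co <- manual_cohort(vals, c("tumor", "normal"))
  expect_equal(coexpression_fraction(co, rownames(vals), "CT01", 0), 1)
  expect_equal(coexpression_fraction(co, rownames(vals), "CT01", 2), 1)
  expect_equal(coexpression_fraction(co, rownames(vals), "CT01", 3), 0)

  cfg <- small_config(seed = 21)
  cohort <- generate_cohort(cfg)
  fr <- vapply(0:3, function(k) {
    coexpression_fraction(cohort, cfg$planted_tfs, "CT01", k)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  # overexpression is non-increasing in the margin
  margins <- c(0, 0.5, 1, 2)
  ov <- vapply(margins, function(m) {
    overexpression_fraction(cohort, "NFKB1", "CT01", margin = m)
  }, numeric(1))
  expect_true(all(diff(ov) <= 0))
})

test_that("hypergeometric enrichment matches hand and edge cases", {
  uni <- sprintf("U%02d", 1:10)
  sets <- list(big = uni[1:5])
  # overlap 4 of query 4 against a 5-set in a 10-universe: 5/210
  res <- enrich_gene_sets(uni[1:4], uni, sets)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$overlap, 4)

  # zero overlap is the vacuous tail
  res0 <- enrich_gene_sets(uni[6:9], uni, list(s = uni[1:5]))
  expect_equal(res0$p_value, 1)
  # a set equal to the universe is saturated
  resU <- enrich_gene_sets(uni[1:4], uni, list(all = uni))
  expect_equal(resU$p_value, 1)
  expect_equal(resU$overlap, 4)

  expect_error(enrich_gene_sets(c(uni[1], "ZZ"), uni, sets), "ZZ")

  # BH adjustment and ordering
  multi <- enrich_gene_sets(uni[1:4], uni,
                            list(a = uni[1:5], b = uni[7:10]))
  expect_true(all(diff(multi$p_value) >= 0))
  expect_true(all(multi$adjusted_p >= multi$p_value))
})

test_that("enrichment p-values equal exhaustive enumeration", {
  # every universe size up to 12, a grid of set and query sizes
  for (N in c(5L, 8L, 12L)) {
    uni <- sprintf("U%02d", seq_len(N))
    for (K in c(2L, N %/% 2L, N - 1L)) {
      for (n in c(1L, N %/% 2L)) {
        query <- uni[seq_len(n)]
        sets <- list(s = uni[seq_len(K)])
        p <- enrich_gene_sets(query, uni, sets)$p_value
        k <- length(intersect(query, sets$s))
        expect_equal(p, enum_hyper_tail(N, K, n, k), tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("evidence ranking orders by total with alphabetical ties", {
  fc <- manual_fc(matrix(2, 4, 3), matrix(0, 4, 3))
  genes <- fc$gene
  sets <- list("GO:0016049" = genes, "GO:0001525" = character(0))
  cand <- select_tfs(fc, genes, sets)
  ev <- data.frame(gene = genes,
                   cell_growth_plus_angiogenesis = c(1, 5, 1, 1),
                   cell_growth_or_angiogenesis = c(9, 5, 9, 2),
                   cell_growth = c(5, 3, 5, 1),
                   angiogenesis = c(5, 1, 5, 2))
  ranked <- rank_by_evidence(cand, ev)
  # G001 and G003 tie at 20; alphabetical order breaks the tie
  expect_equal(top_tfs(ranked, 4), c("G001", "G003", "G002", "G004"))
  expect_setequal(ranked$rank, 1:4)

  single <- select_tfs(manual_fc(matrix(2, 1, 3), matrix(0, 1, 3)),
                       "G001", list("GO:0016049" = "G001",
                                    "GO:0001525" = character(0)))
  r1 <- rank_by_evidence(single, ev[1, ])
  expect_equal(r1$rank, 1L)

  expect_error(rank_by_evidence(cand, ev[-2, ]), "G002")
})

test_that("the synthetic evidence table ranks the three chosen TFs first", {
  path <- system.file("extdata", "evidence_table1_synthetic.tsv",
                      package = "promoterforge")
  ev <- read_evidence(path)
  expect_equal(nrow(ev), 19)
  fc <- manual_fc(matrix(2, 19, 3), matrix(0, 19, 3))
  fc$gene <- ev$gene  # place all 19 candidates in the funnel
  sets <- list("GO:0016049" = ev$gene, "GO:0001525" = character(0))
  cand <- select_tfs(fc, ev$gene, sets)
  ranked <- rank_by_evidence(cand, ev)
  expect_setequal(top_tfs(ranked), c("HIF1A", "CREB1", "NFKB1"))
  expect_equal(sum(ranked$well_studied), 9)
})
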