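wells_from_fcs <- function(fc_by_gene) {
  # one included sample well per replicate with prescribed fold-changes
  purrr::imap_dfr(fc_by_gene, function(fcs, gene) {
    tibble::tibble(
      plate_id = "P001", well_id = "A1",
      replicate = seq_along(fcs), sirna_id = gene, role = "sample",
      cell_count = 500L, mcherry_mean = NA_real_, yfp_mean = NA_real_,
      mcherry_fc = fcs, yfp_fc = fcs, included = TRUE
    )
  })
}

test_that("replicate aggregation follows the log2-then-average convention", {
  wells <- wells_from_fcs(list(flat = c(1, 1, 1), g2 = c(2, 2, 4)))
  scores <- aggregate_replicates(wells)
  flat <- dplyr::filter(scores, gene_id == "flat")
  expect_equal(flat$mcherry_log2fc_mean, 0)
  expect_equal(flat$mcherry_log2fc_sd, 0)
  g2 <- dplyr::filter(scores, gene_id == "g2")
  expect_equal(g2$mcherry_log2fc_mean, 4 / 3)
  expect_equal(g2$mcherry_log2fc_sd, sd(c(1, 1, 2)))
  expect_equal(g2$mcherry_log2fc_sd, 0.5773503, tolerance = 1e-7)
})

test_that("linear fold-change SD drives the percent robustness metric", {
  wells <- wells_from_fcs(list(g1 = c(1.0, 1.5)))
  scores <- aggregate_replicates(wells)
  expect_equal(scores$fc_sd_pct, 100 * sd(c(1, 1.5)))
  expect_equal(scores$fc_sd_pct, 35.35534, tolerance = 1e-5)
  rep_summary <- robustness_report(scores, sd_threshold_pct = 25)
  expect_equal(rep_summary$n_above_threshold, 1)
})

test_that("genes with too few included replicates are dropped and reported", {
  wells <- wells_from_fcs(list(good = c(1, 1.1, 0.9), poor = c(1, 1.2, 1.1)))
  wells$included[wells$sirna_id == "poor" & wells$replicate <= 2] <- FALSE
  scores <- aggregate_replicates(wells, min_replicates = 2)
  expect_false("poor" %in% scores$gene_id)
  expect_true("poor" %in% attr(scores, "dropped")$gene_id)
})

test_that("two-tailed selection takes floor(fraction * N) per tail", {
  scores <- manual_scores(seq_len(40))
  hits <- call_hits(scores)
  expect_equal(sum(hits$hit), 2)
  expect_equal(hits$direction[hits$gene_id == "g001"], "down")
  expect_equal(hits$direction[hits$gene_id == "g040"], "up")
  for (n in c(40, 81, 1000, 16653)) {
    k <- floor(0.025 * n)
    hh <- call_hits(manual_scores(seq_len(n)))
    expect_equal(sum(hh$hit), 2 * k)
    expect_equal(sum(hh$direction == "up"), k)
  }
})

test_that("tie-breaking is deterministic and order-invariant", {
  scores <- manual_scores(rep(0, 200))
  h1 <- call_hits(scores)
  shuffled <- scores[withr::with_seed(3, sample.int(200)), ]
  h2 <- call_hits(shuffled)
  expect_identical(dplyr::arrange(h1, gene_id), dplyr::arrange(h2, gene_id))
  expect_equal(sum(h1$hit), 2 * floor(0.025 * 200))
  # under complete ties the tails are the lexicographic extremes
  expect_true(all(sort(h1$gene_id[h1$direction == "down"]) ==
                    sprintf("g%03d", 1:5)))
})

test_that("hit count follows 2*floor(fraction*N) for randomized sizes", {
  withr::with_seed(11, {
    for (i in 1:15) {
      n <- sample(50:5000, 1)
      frac <- runif(1, 0.005, 0.2)
      if (floor(frac * n) < 1) next
      hh <- call_hits(manual_scores(rnorm(n)), tail_fraction = frac)
      expect_equal(sum(hh$hit), 2 * floor(frac * n))
    }
  })
})

test_that("strengthening a gene's up-effect never evicts it from the up tail", {
  withr::with_seed(21, {
    scores <- manual_scores(rnorm(300))
    hits <- call_hits(scores)
    up_gene <- hits$gene_id[hits$direction == "up"][1]
    for (bump in c(0.5, 2, 10)) {
      scores2 <- scores
      scores2$mcherry_log2fc_mean[scores2$gene_id == up_gene] <-
        scores$mcherry_log2fc_mean[scores$gene_id == up_gene] + bump
      hits2 <- call_hits(scores2)
      expect_equal(hits2$direction[hits2$gene_id == up_gene], "up")
    }
  })
})

test_that("too few genes for a full tail is a sizing error", {
  expect_error(call_hits(manual_scores(seq_len(10))),
               class = "appscreen_sizing_error")
})

test_that("robustness report is zero for perfectly reproducible genes", {
  wells <- wells_from_fcs(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  scores <- aggregate_replicates(wells)
  rr <- robustness_report(scores)
  expect_equal(rr$mean_fc_sd_pct, 0)
  expect_equal(rr$n_above_threshold, 0)
})

test_that("injected strong effects are recalled as hits at default noise", {
  n_genes <- 2000
  recalls <- vapply(1:20, function(s) {
    effects <- simulate_gene_effects(n_genes, seed = 1000 + s)
    sim <- simulate_screen(screen_sim_config(seed = 1000 + s), effects)
    wells <- normalize_wells(filter_wells(sim$wells, min_cells = 0))
    hits <- call_hits(aggregate_replicates(wells))
    strong <- effects$gene_id[abs(effects$mcherry_log2_effect) >= 1]
    mean(strong %in% hits$gene_id[hits$hit])
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})
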