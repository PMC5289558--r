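test_that("set logic assigns convergent, resistant, divergent, unchanged", {
  ids <- c("A", "B", "C", "D", "E")
  esc <- fake_contrast(ids, c("up", "up", "up", "none", "none"))
  ip <- fake_contrast(ids, c("none", "up", "up", "up", "none"))
  tab <- classify_responders(esc, ip)
  lookup <- setNames(tab$class, tab$gene_id)
  expect_equal(lookup[["B"]], "convergent")
  expect_equal(lookup[["C"]], "convergent")
  expect_equal(lookup[["A"]], "resistant")
  expect_equal(lookup[["D"]], "divergent")
  expect_equal(lookup[["E"]], "unchanged")
  expect_true(all(tab$stratum[tab$class != "unchanged"] == "up"))
  expect_false(any(tab$conflict))
})

test_that("no DEGs anywhere leaves every gene unchanged", {
  ids <- paste0("g", 1:10)
  tab <- classify_responders(fake_contrast(ids, "none"),
                             fake_contrast(ids, "none"))
  expect_true(all(tab$class == "unchanged"))
  expect_true(all(tab$stratum == "none"))
})

test_that("conflicting directions yield two flagged stratum records", {
  ids <- c("X", "Y")
  esc <- fake_contrast(ids, c("up", "none"))
  ip <- fake_contrast(ids, c("down", "none"))
  tab <- classify_responders(esc, ip)
  xr <- tab[tab$gene_id == "X", ]
  expect_equal(nrow(xr), 2)
  expect_true(all(xr$conflict))
  expect_setequal(paste(xr$class, xr$stratum),
                  c("resistant up", "divergent down"))
  expect_equal(nrow(tab[tab$gene_id == "Y", ]), 1)
})

test_that("classification partitions the gene universe per stratum", {
  st <- default_study()
  e <- call_degs(st$expression, "ESC", "somatic")
  i <- call_degs(st$expression, "iPSCp", "somatic")
  tab <- classify_responders(e, i)
  non_conflict <- tab[!tab$conflict, ]
  expect_equal(anyDuplicated(non_conflict$gene_id), 0)
  expect_equal(nrow(tab),
               length(unique(tab$gene_id)) + sum(tab$conflict) / 2)
  expect_equal(sum(attr(tab, "class_counts")), nrow(tab))
  expect_error(classify_responders(e, i[-1, ]), "universes differ")
})

test_that("stratum fold-change correlation matches the direct formula", {
  ids <- paste0("g", 1:4)
  esc <- fake_contrast(ids, "up", log2fc = c(1, 2, 3, 0.5))
  ip <- fake_contrast(ids, "up", log2fc = c(0.9, 2.1, 2.8, 0.6))
  r <- class_fc_correlation(esc, ip, "up")
  x <- c(1, 2, 3, 0.5); y <- c(0.9, 2.1, 2.8, 0.6)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, direct)
  expect_equal(round(r, 3), 0.993)
  expect_equal(class_fc_correlation(esc, esc, "up"), 1.0)
  few <- fake_contrast(ids, c("up", "up", "none", "none"))
  expect_warning(r2 <- class_fc_correlation(few, ip, "up"), "fewer than 3")
  expect_true(is.na(r2))
})

test_that("class mark summary aggregates densities per class and stratum", {
  ids <- c("A", "B", "C")
  tab <- classify_responders(fake_contrast(ids, c("up", "up", "none")),
                             fake_contrast(ids, c("up", "none", "none")))
  const_density <- function(x) {
    structure(setNames(rep(x, 3), ids), class = "gene_density")
  }
  dens <- list(ESC = list(H3K4me3 = const_density(7), H3K27me3 = const_density(7)),
               somatic = list(H3K4me3 = const_density(7), H3K27me3 = const_density(7)))
  sm <- class_mark_summary(tab, dens)
  expect_true(all(sm$mean_density == 7))
  expect_true(all(sm$median_density == 7))
  # single-gene classes report that gene's density
  dens$ESC$H3K4me3 <- structure(setNames(c(1, 2, 3), ids), class = "gene_density")
  sm2 <- class_mark_summary(tab, dens)
  conv <- sm2[sm2$class == "convergent" & sm2$cell_type == "ESC" &
              sm2$mark == "H3K4me3", ]
  expect_equal(conv$mean_density, 1)  # gene A alone is convergent
  expect_equal(conv$n, 1)
  expect_error(class_mark_summary(tab, list(ESC = list(H3K4me3 = const_density(1)))),
               "missing mark")
})

test_that("direction percentages sum to 100 and match simple cases", {
  ids <- paste0("g", 1:10)
  k4 <- setNames(rep(0, 10), ids)
  none <- fc_category_percentages(k4, k4, fake_contrast(ids, "none"))
  expect_equal(unname(none$percentages), c(0, 0, 100))
  mixed <- fc_category_percentages(k4, k4,
                                   fake_contrast(ids, c("up", "down", rep("none", 8))))
  expect_equal(unname(mixed$percentages), c(10, 10, 80))
  expect_equal(sum(mixed$percentages), 100, tolerance = 1e-9)
  expect_equal(nrow(mixed$table), 10)
  expect_error(fc_category_percentages(k4[-1], k4, fake_contrast(ids, "none")),
               "universes")
})

test_that("DEG overlap reports set arithmetic exactly", {
  ids <- c("A", "B", "C", "D", "E", "F")
  c1 <- fake_contrast(ids, c("up", "up", "up", "none", "none", "none"))
  c2 <- fake_contrast(ids, c("none", "up", "up", "up", "up", "none"))
  ov <- deg_overlap(list(one = c1, two = c2), direction = "up")
  expect_equal(unname(ov$sizes), c(3L, 4L))
  expect_equal(ov$n_common, 2)
  expect_equal(ov$n_union, 5)
  expect_equal(ov$fraction_common, 0.4)
  expect_equal(ov$pct_common, 40)
  same <- deg_overlap(list(c1, c1), direction = "up")
  expect_equal(same$fraction_common, 1.0)
  disjoint <- deg_overlap(list(c1, fake_contrast(ids, c(rep("none", 3), "up", "up", "up"))),
                          direction = "up")
  expect_equal(disjoint$fraction_common, 0.0)
})

test_that("recovery improves monotonically with effect size", {
  f1 <- function(tab, cls) {
    s <- recovery_stats(tab, cls)
    2 / (1 / s[["precision"]] + 1 / s[["recall"]])
  }
  f1s <- vapply(c(1.0, 2.0, 3.0), function(eff) {
    cfg <- sim_config(n_genes = 600L, chrom_length = 6e6, n_chromosomes = 1L,
                      expr_effect = eff, seed = 19)
    ann <- simulate_genome(cfg)
    truth <- assign_truth(ann, cfg)
    expr <- simulate_expression(truth, cfg)
    tab <- add_truth(classify_responders(call_degs(expr, "ESC", "somatic"),
                                         call_degs(expr, "iPSCp", "somatic")),
                     truth)
    min(f1(tab, "convergent"), f1(tab, "resistant"))
  }, numeric(1))
  expect_true(all(diff(f1s) >= 0))
})
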