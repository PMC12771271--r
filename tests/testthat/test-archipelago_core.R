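test_that("anchors are member-coordinate means and lie within member range", {
  v <- tiny_variants()
  ax <- build_axis(v)
  a <- anchor_sets(tiny_sets(), tiny_membership(), v, ax)
  # singleton behaviour via a one-member set
  a1 <- anchor_sets(data.frame(set_id = "S", p = 0.5), list(S = "v1"), v, ax)
  expect_equal(as.numeric(a1), to_cumulative(ax, "1", 100))
  # midpoint of two members
  x <- to_cumulative(ax, v$chrom, v$pos)
  expect_equal(unname(a["A"]), (x[1] + x[2]) / 2)
  expect_true(all(a >= tapply(x, c("A", "A", "B", "B"), min)[names(a)]))
  expect_true(all(a <= tapply(x, c("A", "A", "B", "B"), max)[names(a)]))
})

test_that("anchors equal a brute-force summation oracle on random sets", {
  sim <- simulate_dataset(sim_params(n_variants = 2000L, set_size = 20L, seed = 21L))
  ax <- build_axis(sim$variants)
  anchors <- anchor_sets(sim$sets, sim$membership, sim$variants, ax)
  x <- setNames(to_cumulative(ax, sim$variants$chrom, sim$variants$pos),
                sim$variants$variant_id)
  for (sid in names(anchors)) {
    expect_equal(unname(anchors[sid]), oracle_mean(x[sim$membership[[sid]]]),
                 tolerance = 1e-12)
    expect_gte(anchors[[sid]], min(x[sim$membership[[sid]]]))
    expect_lte(anchors[[sid]], max(x[sim$membership[[sid]]]))
  }
})

test_that("unresolvable members are excluded; empty sets drop or error", {
  v <- tiny_variants()
  ax <- build_axis(v)
  mem <- list(A = c("v1", "ghost"), B = c("nope1", "nope2"))
  sets <- tiny_sets()
  expect_warning(
    expect_warning(a <- anchor_sets(sets, mem, v, ax), "no matching variant"),
    "zero resolvable")
  expect_equal(names(a), "A")
  expect_equal(as.numeric(a), to_cumulative(ax, "1", 100))
  expect_error(
    suppressWarnings(anchor_sets(sets, mem, v, ax, on_empty = "error")),
    class = "arch_input_error")
})

test_that("rank_sets orders by ascending P with lexicographic tie-break", {
  expect_equal(rank_sets(data.frame(set_id = c("A", "B"), p = c(0.01, 0.001))),
               c("B", "A"))
  expect_equal(rank_sets(data.frame(set_id = c("B", "A"), p = c(0.01, 0.01))),
               c("A", "B"))
  sim <- simulate_dataset(sim_params(seed = 2L))
  r <- rank_sets(sim$sets)
  # independent sort oracle
  oracle <- sim$sets$set_id[order(sim$sets$p, sim$sets$set_id)]
  expect_identical(r, oracle)
})

test_that("dispersion identity, tie placement and even spacing behave as specified", {
  a <- c(A = 1000)
  expect_identical(disperse(a, "A", mode = "priority", min_gap = 10), a)
  expect_identical(disperse(a, "A", mode = "none", min_gap = 10), a)

  # exact tie: B keeps its anchor, A pushed to the +Inf side on a room tie
  tie <- c(A = 1000, B = 1000)
  out <- disperse(tie, c("B", "A"), mode = "priority", min_gap = 10,
                  axis_range = c(0, 2000))
  expect_equal(out[["B"]], 1000)
  expect_equal(out[["A"]], 1010)
  # roomier left side pulls the weaker point left instead
  out_l <- disperse(tie, c("B", "A"), mode = "priority", min_gap = 10,
                    axis_range = c(0, 1100))
  expect_equal(out_l[["B"]], 1000)
  expect_equal(out_l[["A"]], 990)

  ev <- disperse(c(A = 100, B = 500, C = 900), c("A", "B", "C"), mode = "even")
  expect_equal(ev, c(A = 100, B = 500, C = 900))
  ev2 <- disperse(c(A = 100, B = 120, C = 900), c("C", "B", "A"), mode = "even")
  expect_equal(sort(unname(ev2)), c(100, 500, 900))
  expect_lt(ev2[["A"]], ev2[["B"]])  # anchor-rank order kept
})

test_that("priority dispersion satisfies gap, order and strongest-fixed over random configs", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(5:60, 1)
    # clustered anchors force conflicts
    anchors <- setNames(round(runif(m, 0, 1e4) * sample(c(1, 0.01), m, TRUE)),
                        sprintf("s%02d", seq_len(m)))
    p <- runif(m)
    sets <- data.frame(set_id = names(anchors), p = p)
    pri <- rank_sets(sets)
    gap <- runif(1, 1, 1e4 / m)
    out <- disperse(anchors, pri, mode = "priority", min_gap = gap,
                    axis_range = c(0, 1.1e4))
    # all pairwise gaps
    d <- abs(outer(out, out, `-`))
    expect_true(all(d[upper.tri(d)] >= gap - 1e-9))
    # anchor-rank order preserved (ties allowed to resolve either side)
    ord_a <- order(anchors)
    no_tie <- diff(anchors[ord_a]) > 0
    expect_true(all(diff(out[ord_a])[no_tie] > 0))
    # strongest keeps its anchor
    expect_identical(out[[pri[1]]], anchors[[pri[1]]])
    # mode none is the identity
    expect_identical(disperse(anchors, pri, mode = "none", min_gap = gap),
                     anchors)
  }
})

test_that("infeasible min_gap errors with a suggested feasible value", {
  a <- c(A = 1, B = 2, C = 3)
  expect_error(disperse(a, c("A", "B", "C"), mode = "priority", min_gap = 100,
                        axis_range = c(0, 10)),
               "min_gap", class = "arch_config_error")
})

test_that("threshold arithmetic is alpha over the number of set tests", {
  expect_equal(compute_threshold(0.05, 250), 0.0002)
  expect_equal(compute_threshold(0.05, 1), 0.05)
  expect_equal(compute_threshold(0.05, 10), 0.005)
  for (n in c(3, 17, 941)) {
    expect_equal(compute_threshold(0.05, n) * n, 0.05)
  }
  expect_error(compute_threshold(0.05, 0), class = "arch_config_error")
  expect_error(compute_threshold(1.2, 10), class = "arch_config_error")
})

test_that("significance flags are strict and idempotent", {
  pts <- data.frame(id = c("s1", "s2", "v1"), layer = c("set", "set", "variant"),
                    p = c(0.0002, 1e-5, 1e-9), significant = FALSE)
  f <- flag_significant(pts, 0.0002)
  expect_false(f$significant[1])  # boundary is not significant
  expect_true(f$significant[2])
  expect_false(f$significant[3])  # no variant threshold supplied
  f2 <- flag_significant(f, 0.0002)
  expect_identical(f, f2)
  fv <- flag_significant(pts, 0.0002, threshold_variant = 1e-8)
  expect_true(fv$significant[3])
})

test_that("edge building is sound and complete under both modes", {
  sets <- tiny_sets(); mem <- tiny_membership()
  expect_equal(nrow(build_edges(sets, mem, character(0), TRUE)), 0L)
  e <- build_edges(sets, mem, "B", TRUE)
  expect_equal(nrow(e), 2L)
  expect_true(all(e$set_id == "B"))
  e_all <- build_edges(sets, mem, "B", FALSE)
  expect_equal(nrow(e_all), 4L)
  expect_equal(sum(e_all$significant), 2L)
})

test_that("assembled layout has the expected structure and counts", {
  v <- tiny_variants()[1, ]
  s <- data.frame(set_id = "S", p = 0.5)
  lay <- assemble_layout(v, s, list(S = "v1"))
  expect_equal(nrow(lay$points), 2L)
  expect_equal(lay$points$x[1], lay$points$x[2])  # singleton set sits on its variant

  sim <- simulate_dataset(sim_params(seed = 4L))
  lay <- assemble_layout(sim$variants, sim$sets, sim$membership)
  expect_equal(nrow(lay$points), 5250L)
  expect_equal(sum(lay$points$layer == "variant"), 5000L)
  expect_equal(sum(lay$points$layer == "set"), 250L)
  expect_equal(lay$threshold, 0.05 / 250)
  expect_equal(sum(lay$points$significant & lay$points$layer == "set"), 2L)
  expect_identical(sort(unique(lay$points$id[lay$points$layer == "set" &
                                             lay$points$significant])),
                   sim$spiked)
  # y is exactly -log10(p)
  expect_identical(lay$points$y, -log10(lay$points$p))
  # variant colour groups alternate with chromosome parity
  vpts <- lay$points[lay$points$layer == "variant", ]
  parity <- ((match(vpts$chrom, lay$axis$chrom_order) - 1L) %% 2L) + 1L
  expect_identical(vpts$colour_group, parity)
})

test_that("multi-chromosome sets carry no chromosome label", {
  v <- tiny_variants()
  s <- data.frame(set_id = c("mono", "multi"), p = c(0.5, 0.5))
  mem <- list(mono = c("v1", "v2"), multi = c("v2", "v3"))
  lay <- assemble_layout(v, s, mem)
  sp <- lay$points[lay$points$layer == "set", ]
  expect_equal(sp$chrom[sp$id == "mono"], "1")
  expect_true(is.na(sp$chrom[sp$id == "multi"]))
})

test_that("layout is invariant to input row order", {
  sim <- simulate_dataset(sim_params(n_variants = 400L, seed = 6L))
  lay1 <- assemble_layout(sim$variants, sim$sets, sim$membership)
  set.seed(1)
  v2 <- sim$variants[sample(nrow(sim$variants)), ]
  s2 <- sim$sets[sample(nrow(sim$sets)), ]
  m2 <- sim$membership[sample(names(sim$membership))]
  lay2 <- assemble_layout(v2, s2, m2)
  expect_equal(lay1$points, lay2$points)
  expect_equal(lay1$threshold, lay2$threshold)
})

test_that("explicit thresholds and variant-layer thresholds are honoured", {
  sim <- simulate_dataset(sim_params(n_variants = 200L, seed = 8L))
  lay <- assemble_layout(sim$variants, sim$sets, sim$membership,
                         options = arch_options(threshold = 0.5,
                                                threshold_variant = 0.9))
  expect_equal(lay$threshold, 0.5)
  vp <- lay$points[lay$points$layer == "variant", ]
  expect_identical(vp$significant, vp$p < 0.9)
  expect_error(arch_options(threshold = 2), class = "arch_config_error")
})

test_that("copy_set_x_to_variants maps member variants onto their set anchor", {
  v <- tiny_variants()
  s <- data.frame(set_id = "S", p = 1e-6)  # significant at any threshold
  lay <- assemble_layout(v, s, list(S = c("v1", "v2")),
                         options = arch_options(copy_set_x_to_variants = TRUE))
  sx <- lay$points$x[lay$points$layer == "set"]
  expect_equal(lay$points$x[lay$points$id %in% c("v1", "v2")], rep(sx, 2))
  expect_false(isTRUE(all.equal(lay$points$x[lay$points$id == "v3"], sx)))
})

test_that("af_summary matches an independent oracle and handles edge cases", {
  v <- tiny_variants()
  s <- af_summary(v, c("v1", "v2"))
  expect_equal(s, list(n = 2L, mean_af = 0.2, min_af = 0.1, max_af = 0.3))
  s1 <- af_summary(v, "v3")
  expect_equal(s1$n, 1L)
  expect_equal(s1$mean_af, 0.25)
  expect_equal(s1$min_af, s1$max_af)

  sim <- simulate_dataset(sim_params(n_variants = 300L, seed = 10L))
  sel <- sim$membership[[1]]
  got <- af_summary(sim$variants, sel)
  afs <- sim$variants$af[match(sel, sim$variants$variant_id)]
  expect_equal(got$mean_af, oracle_mean(afs))
  expect_equal(got$min_af, min(afs))
  expect_equal(got$max_af, max(afs))

  expect_message(e <- af_summary(v, "absent"), "empty")
  expect_equal(e$n, 0L)
  expect_true(is.na(e$mean_af))
  v_no_af <- v[, setdiff(names(v), "af")]
  expect_error(af_summary(v_no_af, "v1"), class = "arch_input_error")
})
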