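test_that("spearman_edges reproduces monotone and anti-monotone extremes", {
  e <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("E1", paste0("s", 1:5)))
  p_up <- matrix(c(2, 4, 6, 8, 10), 1, dimnames = list("G1", paste0("s", 1:5)))
  p_dn <- matrix(c(5, 4, 3, 2, 1), 1, dimnames = list("G2", paste0("s", 1:5)))
  expect_equal(spearman_edges(e, p_up)$rho, 1)
  expect_equal(spearman_edges(e, p_up)$p, 0)
  expect_equal(spearman_edges(e, p_dn)$rho, -1)
})

test_that("the n = 4 case documents the t-approximation / exact-permutation
           divergence", {
  e <- matrix(1:4, 1, dimnames = list("E1", paste0("s", 1:4)))
  g <- matrix(c(1, 3, 2, 4), 1, dimnames = list("G1", paste0("s", 1:4)))
  approx <- spearman_edges(e, g, p_method = "approx_t")
  expect_equal(approx$rho, 0.8)
  expect_equal(approx$p, 0.2, tolerance = 1e-10)
  exact <- spearman_edges(e, g, p_method = "exact")
  # oracle: exhaustive permutation distribution of rank correlation, n = 4
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rhos <- apply(perms, 1, function(p) cor(1:4, c(1, 3, 2, 4)[p]))
  expect_equal(exact$p, mean(abs(rhos) >= 0.8 - 1e-12))
  expect_equal(exact$p, 1 / 3)
})

test_that("spearman_edges matches the rank-then-Pearson oracle to 1e-12", {
  set.seed(17)
  e <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("E", 1:5),
                                                paste0("s", 1:10)))
  g <- matrix(rnorm(4 * 10), 4, dimnames = list(paste0("G", 1:4),
                                                paste0("s", 1:10)))
  edges <- spearman_edges(e, g)
  for (r in seq_len(nrow(edges))) {
    want <- spearman_oracle(e[edges$source[r], ], g[edges$target[r], ])
    expect_equal(edges$rho[r], want, tolerance = 1e-12)
  }
  # tied values use mid-ranks
  e2 <- matrix(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), 1,
               dimnames = list("E1", paste0("s", 1:10)))
  edges2 <- spearman_edges(e2, g)
  for (r in seq_len(nrow(edges2)))
    expect_equal(edges2$rho[r],
                 spearman_oracle(e2[1, ], g[edges2$target[r], ]),
                 tolerance = 1e-12)
})

test_that("zero-variance features yield NaN and are excluded downstream", {
  e <- matrix(c(rep(1, 6), rnorm(6)), 2, byrow = TRUE,
              dimnames = list(c("Eflat", "Eok"), paste0("s", 1:6)))
  g <- matrix(rnorm(6), 1, dimnames = list("G1", paste0("s", 1:6)))
  edges <- spearman_edges(e, g)
  flat <- edges[edges$source == "Eflat", ]
  expect_true(is.nan(flat$rho) && is.nan(flat$p) && is.nan(flat$q))
  net <- suppressWarnings(build_coexpression_network(edges, rho_min = 0,
                                                     q_max = 1))
  expect_false("Eflat" %in% net$nodes$id)
})

test_that("spearman_edges validates sample alignment", {
  e <- matrix(1:8, 2, dimnames = list(c("E1", "E2"), paste0("s", 1:4)))
  g <- matrix(1:8, 2, dimnames = list(c("G1", "G2"), paste0("x", 1:4)))
  expect_error(spearman_edges(e, g), "sample")
  colnames(g) <- paste0("s", 1:4)
  expect_error(spearman_edges(e[, 1:3], g[, 1:3]), "4 samples")
})

test_that("adjust_bh equals the quadratic-time step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(23)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- adjust_bh(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))  # monotone along sorted p
  }
  # NaN propagates and shrinks the family size m
  q <- adjust_bh(c(0.01, NaN, 0.04))
  expect_true(is.nan(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.04)))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("build_coexpression_network applies |rho| and q thresholds", {
  edges <- data.frame(
    source = c("E1", "E1", "E2"), target = c("G1", "G2", "G1"),
    kind = "coexpr", rho = c(0.29, -0.9, 0.5),
    p = c(0.001, 0.01, 0.2), q = c(0.001, 0.01, 0.2),
    evidence = "", stringsAsFactors = FALSE)
  net <- build_coexpression_network(edges)
  expect_equal(nrow(net$edges), 1L)        # only the |rho|=0.9, q=0.01 edge
  expect_equal(net$edges$rho, -0.9)
  expect_setequal(net$nodes$id, c("E1", "G2"))
  expect_warning(empty <- build_coexpression_network(edges, rho_min = 0.99),
                 "no edges")
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("regulatory_overlaps deduplicates peaks into counted edges", {
  ern <- iv("c", 1000, 2000, name = "E1")
  peaks <- list(
    list(regulator_id = "TF1", kind = "tf",
         intervals = iv("c", 1500, 1600)),
    list(regulator_id = "RBP1", kind = "rbp",
         intervals = iv("c", c(1100, 1200, 1900), c(1150, 1300, 2100))),
    list(regulator_id = "TF2", kind = "tf",
         intervals = iv("c", 2000, 2100))  # abuts: no edge
  )
  edges <- regulatory_overlaps(ern, peaks)
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$evidence[edges$target == "RBP1"], "3")
  expect_equal(edges$kind[edges$target == "TF1"], "tf")
  expect_false("TF2" %in% edges$target)
})

test_that("loop_edges links eRNAs to promoters through anchors and records
           promoterless eRNA-mediated loops", {
  ern <- iv("c", 10000, 11000, name = "E1")
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "c",
                      tss = c(50000L, 80000L))
  loops <- data.frame(
    chrom1 = "c", start1 = c(10500L, 10200L, 10300L),
    end1 = c(10600L, 10250L, 10400L),
    chrom2 = "c", start2 = c(49000L, 10800L, 82001L),
    end2 = c(49500L, 10900L, 82100L), score = NA_real_)
  edges <- loop_edges(ern, loops, genes, promoter_flank = 2000)
  # loop 1: anchor2 [49000,49500) overlaps promoter [48000,52000) -> edge
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$source, "E1")
  expect_equal(edges$target, "G1")
  med <- attr(edges, "mediated_loops")
  expect_setequal(med$loop, c(1L, 2L, 3L))
  # loop 3: anchor2 starts at tss+2001 with flank 2000 -> mediated, no edge
  expect_false(med$has_promoter_partner[med$loop == 3])
  # boundary: anchor starting exactly at tss+flank-1 still overlaps
  loops4 <- data.frame(chrom1 = "c", start1 = 10500L, end1 = 10600L,
                       chrom2 = "c", start2 = 81999L, end2 = 82100L,
                       score = NA_real_)
  expect_equal(loop_edges(ern, loops4, genes, 2000)$target, "G2")
})

test_that("intersect_networks is commutative, idempotent, and bounded by
           both inputs", {
  a <- net_from_pairs(rbind(c("E1", "G1"), c("E1", "G2"), c("E2", "G1")))
  expect_equal(intersect_networks(a, a)$edges[, c("source", "target")],
               a$edges[, c("source", "target")])
  # unordered match across kinds
  b <- as_network(data.frame(source = "G1", target = "E1", kind = "loop",
                             stringsAsFactors = FALSE))
  ab <- intersect_networks(a, b)
  expect_equal(nrow(ab$edges), 1L)
  expect_equal(ab$edges$evidence, "a:coexpr;b:loop")
  # disjoint edges sharing nodes keep the nodes, zero edges
  c_ <- as_network(data.frame(source = "E2", target = "G2", kind = "coexpr"))
  ac <- intersect_networks(a, c_)
  expect_setequal(ac$nodes$id, c("E2", "G2"))
  expect_equal(nrow(ac$edges), 0L)
  set.seed(31)
  ids <- c(paste0("E", 1:4), paste0("G", 1:8))
  for (rep in 1:20) {
    n1 <- random_net(ids, 0.3)
    n2 <- random_net(ids, 0.3)
    i12 <- intersect_networks(n1, n2)
    i21 <- intersect_networks(n2, n1)
    key <- function(net) sort(paste(pmin(net$edges$source, net$edges$target),
                                    pmax(net$edges$source, net$edges$target)))
    expect_identical(key(i12), key(i21))
    expect_identical(sort(i12$nodes$id), sort(i21$nodes$id))
    expect_true(all(key(i12) %in% key(n1)) && all(key(i12) %in% key(n2)))
  }
})

test_that("planted co-expressed pairs are recovered at default thresholds
           with controlled FDR", {
  spec <- fixture_spec(seed = 99, preset = "network-heavy")
  ex <- make_expression(spec, sprintf("E%02d", 1:26), sprintf("G%02d", 1:20))
  expect_equal(nrow(ex$planted), 20L)
  edges <- spearman_edges(ex$erna, ex$pcg)
  net <- build_coexpression_network(edges)
  got <- paste(net$edges$source, net$edges$target)
  planted <- paste(ex$planted$erna, ex$planted$pcg)
  recall <- mean(planted %in% got)
  fdr <- if (length(got)) mean(!(got %in% planted)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
})
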