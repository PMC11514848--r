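clique_pairs <- function(ids) t(combn(ids, 2))

test_that("two bridged 4-cliques split into exactly the two cliques", {
  a <- paste0("a", 1:4)
  b <- paste0("b", 1:4)
  net <- net_from_pairs(rbind(clique_pairs(a), clique_pairs(b),
                              c("a1", "b1")))
  mods <- extract_modules(net)
  expect_length(mods, 2L)
  expect_setequal(lapply(mods, `[[`, "members"), list(a, b))
  expect_equal(vapply(mods, `[[`, 0, "density"), c(1, 1))
})

test_that("a triangle is one module of density 1; edgeless graphs give
           none", {
  tri <- net_from_pairs(rbind(c("x", "y"), c("y", "z"), c("x", "z")))
  mods <- extract_modules(tri)
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$members, c("x", "y", "z"))
  expect_equal(mods[[1]]$density, 1)
  lonely <- as_network(data.frame(source = character(0),
                                  target = character(0),
                                  kind = character(0)))
  expect_length(extract_modules(lonely), 0L)
})

test_that("every emitted module meets the density threshold and modules
           are disjoint, on random graphs", {
  set.seed(41)
  ids <- sprintf("n%02d", 1:14)
  for (rep in 1:60) {
    net <- random_net(ids, runif(1, 0.1, 0.6))
    adj <- ernatools:::adjacency_list(net)
    mods <- extract_modules(net, density_threshold = 0.5,
                            support_threshold = 0.5)
    members <- unlist(lapply(mods, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0L)
    expect_true(all(members %in% net$nodes$id))
    for (m in mods) {
      expect_gte(length(m$members), 2L)
      dens <- module_density(m$members, adj)
      expect_equal(m$density, dens)
      expect_gte(dens, 0.5)
    }
  }
})

test_that("module extraction is deterministic with lexicographic
           tie-breaks", {
  net <- net_from_pairs(rbind(c("b", "c"), c("a", "b"), c("a", "c"),
                              c("d", "e")))
  m1 <- extract_modules(net)
  m2 <- extract_modules(net_from_pairs(rbind(c("d", "e"), c("a", "c"),
                                             c("a", "b"), c("b", "c"))))
  expect_identical(m1, m2)
})

test_that("extract_hubs applies the degree-quantile-with-floor rule", {
  star <- net_from_pairs(cbind("hub", paste0("leaf", 1:10)))
  expect_equal(extract_hubs(star), "hub")
  ring <- net_from_pairs(cbind(paste0("r", 1:6),
                               paste0("r", c(2:6, 1))))
  expect_equal(extract_hubs(ring, min_degree = 5), character(0))
  # two nodes tied at the cutoff are both included
  two <- net_from_pairs(rbind(cbind("h1", paste0("x", 1:5)),
                              cbind("h2", paste0("y", 1:5))))
  hubs <- extract_hubs(two, top_fraction = 0.05, min_degree = 5)
  expect_setequal(hubs, c("h1", "h2"))
})

test_that("hypergeometric enrichment matches the combinatorial tail sum", {
  coll <- gene_set_collection(
    list(S = sprintf("g%02d", 1:6)),
    universe = sprintf("g%02d", 1:20))
  res <- hypergeom_enrich(sprintf("g%02d", c(1, 2, 3, 10, 11)), coll)
  expect_equal(res$k, 3L)
  expect_equal(res$p, hyper_tail_oracle(3, 6, 20, 5), tolerance = 1e-12)
  expect_equal(res$p, 0.13132095, tolerance = 1e-6)
  # k = 0 and set == universe both give p = 1
  res0 <- hypergeom_enrich(sprintf("g%02d", 15:19), coll)
  expect_equal(res0$p, 1)
  collU <- gene_set_collection(list(ALL = sprintf("g%02d", 1:20)))
  expect_equal(hypergeom_enrich(sprintf("g%02d", 1:5), collU)$p, 1)
})

test_that("enrichment p-values match enumeration across (N <= 25, K, n, k)
           and are monotone in k", {
  for (N in c(5L, 12L, 25L)) {
    for (K in seq(1L, N, by = 4L)) {
      for (n in seq(1L, N, by = 5L)) {
        ks <- 0:min(n, K)
        ps <- vapply(ks, function(k)
          if (k == 0) 1 else
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE), 0)
        want <- vapply(ks, hyper_tail_oracle, 0, K = K, N = N, n = n)
        expect_equal(ps, want, tolerance = 1e-10)
        expect_true(all(diff(ps) <= 1e-12))  # non-increasing in k
      }
    }
  }
  # the same tail computation drives hypergeom_enrich
  universe <- sprintf("u%02d", 1:25)
  coll <- gene_set_collection(list(S = universe[1:7]), universe = universe)
  res <- hypergeom_enrich(universe[c(1:4, 20:24)], coll)
  expect_equal(res$p, hyper_tail_oracle(4, 7, 25, 9), tolerance = 1e-12)
})

test_that("enrichment drops out-of-universe ids with a warning and adjusts
           within the collection", {
  coll <- gene_set_collection(list(A = c("g1", "g2", "g3"),
                                   B = c("g4", "g5")),
                              universe = paste0("g", 1:10))
  expect_warning(res <- hypergeom_enrich(c("g1", "g2", "zzz"), coll),
                 "outside the universe")
  expect_equal(unique(res$n), 2L)
  expect_equal(res$q, adjust_bh(res$p))
  expect_error(hypergeom_enrich("g1",
                                gene_set_collection(list(A = "g1"),
                                                    universe = character(0))),
               "empty universe")
})

test_that("annotate_erna enriches neighbor, module and hub queries and the
           planted program ranks first", {
  # eRNA wired to all members of a coherent program among unrelated genes
  program <- sprintf("p%d", 1:6)
  others <- sprintf("q%d", 1:14)
  pairs <- rbind(cbind("E1", program),
                 clique_pairs(program[1:4]),
                 cbind(others[1:6], others[7:12]))
  roles <- stats::setNames(rep("pcg", 20), c(program, others))
  roles["E1"] <- "erna"
  net <- as_network(data.frame(source = pairs[, 1], target = pairs[, 2],
                               kind = "coexpr", stringsAsFactors = FALSE),
                    roles = roles)
  set.seed(5)
  coll <- gene_set_collection(
    list(program_set = program,
         decoy1 = sample(others, 6), decoy2 = sample(others, 6)),
    universe = c(program, others))
  rep <- annotate_erna("E1", net, collection = coll)
  expect_setequal(rep$neighbors$query, program)
  expect_equal(rep$neighbors$enrichment$set_name[1], "program_set")
  # direct tail-sum comparison for the top set
  expect_equal(rep$neighbors$enrichment$p[1],
               hyper_tail_oracle(6, 6, 20, 6), tolerance = 1e-12)
  mod_queries <- lapply(rep$modules, function(m) m$query)
  expect_true(all(vapply(mod_queries, function(q)
    all(q %in% c(program, others)), TRUE)))
  expect_error(annotate_erna("nope", net, collection = coll), "nope")
  # no PCG neighbors -> empty queries with warning
  iso <- as_network(data.frame(source = "E2", target = "E3",
                               kind = "coexpr"),
                    roles = c(E2 = "erna", E3 = "erna"))
  expect_warning(r2 <- annotate_erna("E2", iso, collection = coll),
                 "no PCG neighbors")
  expect_length(r2$neighbors$query, 0L)
})
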