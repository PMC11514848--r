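test_that("filter_transcripts removes on >= 1 bp span overlap with the
           pcg -> repeats -> blacklist reason precedence", {
  txs <- bind_tx(
    tx1("T1", "c", "+", 100, 200),   # 1-bp overlap with pcg
    tx1("T2", "c", "+", 350, 400),   # abuts blacklist: retained
    tx1("T3", "c", "+", 500, 700),   # overlaps repeats AND blacklist
    tx1("T4", "c", "+", 900, 950)    # clean
  )
  res <- filter_transcripts(
    txs,
    pcg = iv("c", 199, 300),
    repeats = iv("c", 600, 650),
    blacklist = iv(c("c", "c"), c(400, 640), c(500, 800))
  )
  expect_setequal(res$retained$transcript_id, c("T2", "T4"))
  expect_equal(res$removal_log$reason[res$removal_log$transcript_id == "T1"],
               "pcg")
  expect_equal(res$removal_log$reason[res$removal_log$transcript_id == "T3"],
               "repeats")
  # partition property: retained + removed = input, no overlap
  expect_setequal(c(res$retained$transcript_id,
                    res$removal_log$transcript_id), txs$transcript_id)
  expect_length(intersect(res$retained$transcript_id,
                          res$removal_log$transcript_id), 0)
})

test_that("exon-level filtering retains intron-only hits that span-level
           removes", {
  txs <- tx1("T1", "c", "+", c(100, 900), c(200, 1000))
  rpt <- iv("c", 400, 500)  # intronic
  expect_equal(nrow(filter_transcripts(txs, repeats = rpt)$removal_log), 1L)
  expect_equal(nrow(filter_transcripts(txs, repeats = rpt,
                                       level = "exon")$removal_log), 0L)
})

test_that("longest ORF scan finds ATG..stop runs over three frames", {
  set.seed(3)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste0,
                         collapse = ""), c("TAA", "TAG", "TGA", "ATG"))
  orf100 <- paste0("ATG", paste(sample(sense, 99, TRUE), collapse = ""),
                   "TAA")
  expect_equal(longest_orf_aa(orf100), 100L)
  expect_equal(longest_orf_aa("CCTTTCCCTT"), 0L)         # no ATG
  expect_equal(longest_orf_aa("ATGAAACCC"), 0L)          # no stop
  expect_equal(longest_orf_aa(paste0("C", orf100)), 100L) # frame 1
  expect_equal(longest_orf_aa(paste0("CC", orf100)), 100L) # frame 2
})

test_that("classify_coding thresholds the ORF and honors external tables", {
  txs <- tx1("T1", "c", "+", 0, 303)
  seq100 <- paste0("ATG", paste(rep("GCA", 99), collapse = ""), "TAA")
  calls <- classify_coding(txs, method = "orf_fallback",
                           sequences = c(T1 = seq100))
  expect_equal(calls$label, "coding")
  expect_equal(calls$score, 100)
  calls99 <- classify_coding(txs, method = "orf_fallback",
                             sequences = c(T1 = seq100), orf_min = 101)
  expect_equal(calls99$label, "noncoding")
  expect_error(classify_coding(txs, method = "orf_fallback",
                               sequences = c(T1 = "ATG")),
               "exonic_length")
  ext <- classify_coding(txs, method = "external_table",
                         table = data.frame(transcript_id = "T1",
                                            label = "noncoding"))
  expect_equal(ext$label, "noncoding")
  expect_equal(ext$method, "external_table")
  expect_true(is.na(ext$score))
  expect_error(classify_coding(txs, method = "external_table",
                               table = data.frame(transcript_id = "TX",
                                                  label = "coding")),
               "T1")
})

test_that("call_ernas applies the TSS-in-enhancer and any-overlap rules at
           half-open boundaries", {
  enh <- iv("c", 4000, 5000, name = "mA,mB")
  at_4999 <- tx1("E1", "c", "+", 4999, 5200)
  at_5000 <- tx1("E2", "c", "+", 5000, 5200)
  span_in <- tx1("E3", "c", "+", 4800, 5200)
  span_in$tss <- 5100L  # TSS outside, span overlapping

  expect_equal(call_ernas(at_4999, enh)$transcript_id, "E1")
  expect_equal(nrow(call_ernas(at_5000, enh)), 0L)
  expect_equal(nrow(call_ernas(span_in, enh, rule = "tss_in_enhancer")), 0L)
  expect_equal(call_ernas(span_in, enh, rule = "any_overlap")$transcript_id,
               "E3")
  got <- call_ernas(at_4999, enh)
  expect_equal(got$markers, "mA,mB")
  expect_equal(got$enhancers[[1]]$start, 4000L)
  expect_equal(nrow(call_ernas(at_4999, enh[0, ])), 0L)
})

test_that("any_overlap calls are a superset of tss_in_enhancer calls", {
  set.seed(21)
  enh <- iv("c", s <- sample(50000, 10), s + 1000L)
  txs <- do.call(bind_tx, lapply(1:40, function(i) {
    st <- sample(50000, 1)
    tx1(sprintf("T%02d", i), "c", sample(c("+", "-"), 1), st, st + 600L)
  }))
  tss_calls <- call_ernas(txs, enh, "tss_in_enhancer")$transcript_id
  any_calls <- call_ernas(txs, enh, "any_overlap")$transcript_id
  expect_true(all(tss_calls %in% any_calls))
})

test_that("adjacent_genes uses closest-edge distance with the 1-Mb window", {
  ern <- iv("c", 10000, 11000, name = "E1")
  genes <- iv(c("c", "c", "c", "d"),
              c(11000, 2e6, 9000, 10000),
              c(12000, 2e6 + 1000, 9500, 11000),
              name = c("gAbut", "gFar", "gNear", "gOtherChrom"))
  adj <- adjacent_genes(ern, genes)
  expect_equal(adj$gene_id, c("gAbut", "gNear"))
  expect_equal(adj$distance, c(0, 500))
  # boundary: exactly window bp away is included, window+1 is not
  g2 <- iv("c", c(11000 + 1e6, 11000 + 1e6 + 1), c(11000 + 1e6 + 10, 2e7),
           name = c("gAtWindow", "gPastWindow"))
  adj2 <- adjacent_genes(ern, g2)
  expect_equal(adj2$gene_id, "gAtWindow")
  # overlap means distance zero; ties sort by gene id
  g3 <- iv("c", c(10500, 10200), c(10600, 10300), name = c("b", "a"))
  adj3 <- adjacent_genes(ern, g3)
  expect_equal(adj3$gene_id, c("a", "b"))
  expect_equal(adj3$distance, c(0, 0))
})

test_that("annotate_regions counts overlapping records per annotation set,
           emitting zero-count rows", {
  ern <- iv("c", 1000, 2000, name = "E1")
  ann <- list(
    mutations = iv("c", c(1100, 1500, 5000), c(1101, 1501, 5001),
                   name = c("m1", "m2", "m3")),
    peaks = iv("c", 999, 1001, name = "p1"),  # straddles by 1 bp
    empty_set = iv("d", 1, 2, name = "x")
  )
  tab <- annotate_regions(ern, ann)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$count[tab$annotation == "mutations"], 2L)
  expect_equal(tab$names[tab$annotation == "mutations"], "m1,m2")
  expect_equal(tab$count[tab$annotation == "peaks"], 1L)
  expect_equal(tab$count[tab$annotation == "empty_set"], 0L)
})

test_that("run_erna_id chains filters, coding gate and calling", {
  spec <- fixture_spec(seed = 5, preset = "tiny")
  ann <- make_annotation(spec)
  enh <- combine_markers(ann$markers, mode = "merge")
  coding <- classify_coding(ann$transcripts, method = "orf_fallback",
                            sequences = ann$sequences)
  res <- run_erna_id(ann$transcripts, enh, pcg = ann$pcg_spans,
                     repeats = ann$repeats, blacklist = ann$blacklist,
                     coding = coding, genes = ann$genes)
  planted <- ann$truth$transcript_id[ann$truth$class == "planted_erna"]
  expect_setequal(res$calls$transcript_id, planted)
  # every call survived both gates
  expect_true(all(res$calls$transcript_id %in%
                    res$noncoding$transcript_id))
  expect_length(intersect(res$calls$transcript_id,
                          res$removal_log$transcript_id), 0)
  expect_true(all(res$adjacent$distance <= 1e6))
})
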