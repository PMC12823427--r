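test_that("mutation notation parses, dropping the reference from mixtures", {
  m <- parse_mutation("K103N/S", "RT")
  expect_equal(m$position, 103L)
  expect_equal(sort(m$observed_aas), c("N", "S"))
  expect_equal(m$reference_aa, "K")

  m <- parse_mutation("M230M/L", "RT")
  expect_equal(m$observed_aas, "L")

  m <- parse_mutation("Q148R", "IN")
  expect_equal(m$position, 148L)
  expect_equal(m$observed_aas, "R")

  m <- parse_mutation("103N", "RT")
  expect_true(is.na(m$reference_aa))
  expect_equal(m$observed_aas, "N")

  ## stop codons are valid observations
  m <- parse_mutation("W88*", "RT")
  expect_equal(m$observed_aas, "*")

  expect_error(parse_mutation("K103", "RT"),
               class = "virosnap_parse_error")
  expect_error(parse_mutation("Kx3N", "RT"),
               class = "virosnap_parse_error")
  err <- tryCatch(parse_mutation("K103N-", "RT"), error = identity)
  expect_match(conditionMessage(err), "offset")
})

test_that("APOBEC evidence comes from signatures or stop codons", {
  lists <- test_lists()
  ev <- has_apobec_evidence(with_char(wt_seq(), 25, "*"), "RT", lists)
  expect_true(ev$evidence)
  expect_equal(ev$kind, "stop_codon")

  ev <- has_apobec_evidence(with_char(wt_seq(), 20, "K"), "RT", lists)
  expect_true(ev$evidence)
  expect_equal(ev$kind, "signature_mutation")

  ev <- has_apobec_evidence(wt_seq(), "RT", lists)
  expect_false(ev$evidence)
  expect_equal(ev$kind, "none")

  ## a mixture containing the signature residue counts
  ev <- has_apobec_evidence(with_char(wt_seq(), 20, "[AK]"), "RT", lists)
  expect_true(ev$evidence)
})

test_that("context mutations are disregarded only with APOBEC evidence", {
  lists <- test_lists()
  e138k <- parse_mutation("E138K", "RT")
  k103n <- parse_mutation("K103N", "RT")
  g118r <- parse_mutation("G118R", "IN")
  hyper_rt <- with_char(wt_seq(), 20, "K")
  hyper_in <- with_char(wt_seq(), 30, "N")

  res <- filter_drms(list(e138k), hyper_rt, "RT", lists)
  expect_length(res$retained, 0)
  expect_length(res$disregarded, 1)
  expect_true(res$apobec_evidence)

  res <- filter_drms(list(g118r), hyper_in, "IN", lists)
  expect_length(res$disregarded, 1)

  ## K103N is not in the context set: retained despite evidence
  res <- filter_drms(list(k103n, e138k), hyper_rt, "RT", lists)
  expect_equal(vapply(res$retained, `[[`, integer(1), "position"), 103L)
  expect_equal(vapply(res$disregarded, `[[`, integer(1), "position"), 138L)

  ## no evidence: everything retained
  res <- filter_drms(list(e138k), wt_seq(), "RT", lists)
  expect_length(res$retained, 1)
  expect_length(res$disregarded, 0)
  expect_false(res$apobec_evidence)

  ## idempotence: filtering the retained set again changes nothing
  res1 <- filter_drms(list(k103n, e138k), hyper_rt, "RT", lists)
  res2 <- filter_drms(res1$retained, hyper_rt, "RT", lists)
  expect_equal(res2$retained, res1$retained)
  expect_length(res2$disregarded, 0)
})

test_that("filter equals the brute-force oracle on random instances", {
  lists <- test_lists()
  set.seed(31)
  aas <- c("A", "K", "I", "N", "R", "S")
  for (rep in 1:200) {
    gene <- sample(c("RT", "IN"), 1)
    ncalls <- sample(0:4, 1)
    calls <- lapply(seq_len(ncalls), function(i) {
      pos <- sample(c(103L, 118L, 138L, 230L, 15L), 1)
      obs <- sample(aas, sample(1:2, 1))
      list(gene = gene, position = pos, reference_aa = "E",
           observed_aas = obs)
    })
    res <- strsplit(wt_seq(), "")[[1]]
    if (runif(1) < 0.3) res[sample(40, 1)] <- "*"
    if (runif(1) < 0.4) res[20] <- "K"
    if (runif(1) < 0.4) res[30] <- "N"
    seqstr <- paste(res, collapse = "")

    got <- filter_drms(calls, seqstr, gene, lists)
    want <- filter_oracle(calls, seqstr, gene, lists)
    expect_equal(got$retained, want$retained)
    expect_equal(got$disregarded, want$disregarded)
    ## partition invariant
    expect_equal(length(got$retained) + length(got$disregarded), ncalls)
    if (length(got$disregarded)) expect_true(got$apobec_evidence)
  }
})

test_that("prevalence matches the fixture and filtering is monotone", {
  ds <- make_fixture()
  lists <- mutation_lists()
  filt <- resistance_prevalence(ds, lists, "rilpivirine",
                                arm = "long_acting")
  expect_equal(filt$numerator, 14L)
  expect_equal(filt$denominator, 208L)
  expect_equal(filt$prevalence, 14 / 208)

  unfilt <- resistance_prevalence(ds, lists, "rilpivirine",
                                  arm = "long_acting", apply_filter = FALSE)
  expect_equal(unfilt$numerator, 25L)
  expect_gte(unfilt$prevalence, filt$prevalence)

  ## no sequences for the gene: empty denominator
  none <- resistance_prevalence(ds, lists, "cabotegravir",
                                arm = "long_acting")
  expect_equal(none$denominator, 0L)
})

test_that("shipped context list is the standard 14-item set", {
  lists <- mutation_lists()
  expect_equal(nrow(lists$context), 14L)
  key <- paste0(lists$context$gene, lists$context$position, lists$context$aa)
  expect_setequal(key, c("RT67N", "RT138K", "RT184I", "RT190E", "RT190S",
                         "RT230I", "IN118R", "IN138K", "IN140R", "IN140S",
                         "IN163K", "IN163R", "IN232N", "IN263K"))
})
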