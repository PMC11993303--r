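# filters: per-read thresholds and pair-aware filtering

test_that("aligned_length walks the CIGAR correctly", {
  expect_identical(aligned_length(c("100M", "10S80M10S", "50M2I48M")),
                   c(100L, 80L, 100L))
  # deletions/skips consume no query
  expect_identical(aligned_length("20M5D20M"), 40L)
  expect_identical(aligned_length("20M100N20M"), 40L)
  expect_identical(aligned_length("5H90M5H"), 90L)
})

test_that("percent_identity is 1 - NM / aligned_length", {
  r <- rec_table("c1", 0, c("100M", "100M", "10S90M"), nm = c(0L, 3L, 9L))
  expect_equal(percent_identity(r), c(1.0, 0.97, 0.90))
  r$nm[2] <- NA_integer_
  expect_error(percent_identity(r), "NM tag absent.*r002")
})

test_that("passes_filters applies inclusive thresholds", {
  r <- rec_table("c1", 0, c("100M", "45M55S"), nm = c(3L, 0L))
  expect_true(all(passes_filters(r, filter_config())))

  cfg <- filter_config(min_percent_identity = 0.97)
  expect_identical(passes_filters(r, cfg), c(TRUE, TRUE))  # 0.97 >= 0.97

  cfg <- filter_config(min_aligned_percent = 0.50)
  expect_identical(passes_filters(r, cfg), c(TRUE, FALSE))  # 45/100 < 0.5

  cfg <- filter_config(min_aligned_length = 46L)
  expect_identical(passes_filters(r, cfg), c(TRUE, FALSE))

  cfg <- filter_config(proper_pairs_only = TRUE)
  expect_identical(passes_filters(r, cfg), c(FALSE, FALSE))
  r2 <- rec_table("c1", 0, "100M", flag = 3L)  # paired + proper
  expect_true(passes_filters(r2, cfg))
})

test_that("fractional thresholds outside [0,1] are rejected", {
  expect_error(filter_config(min_percent_identity = 1.5), "\\[0, 1\\]")
  expect_error(filter_config(min_aligned_percent = -0.1), "\\[0, 1\\]")
})

test_that("pair filtering: independent vs together semantics", {
  # r1 pair: both pass; r2 pair: mate 2 fails identity
  recs <- rbind(
    rec_table("c1", c(10, 200), "100M", nm = 0L, flag = c(99L, 147L),
              qname = c("r1", "r1")),
    rec_table("c1", c(50, 300), "100M", nm = c(0L, 10L),
              flag = c(99L, 147L), qname = c("r2", "r2"))
  )
  cfg_i <- filter_config(min_percent_identity = 0.97,
                         pair_mode = "independent")
  cfg_t <- filter_config(min_percent_identity = 0.97,
                         pair_mode = "together")
  kept_i <- apply_filters(recs, cfg_i)
  kept_t <- apply_filters(recs, cfg_t)
  expect_setequal(paste(kept_i$qname, kept_i$flag),
                  c("r1 99", "r1 147", "r2 99"))
  expect_setequal(paste(kept_t$qname, kept_t$flag),
                  c("r1 99", "r1 147"))  # failing mate discards the pair
})

test_that("orphans in together mode are judged alone with a warning", {
  recs <- rec_table("c1", 10, "100M", nm = 0L, flag = 99L, qname = "lone")
  cfg <- filter_config(min_percent_identity = 0.97, pair_mode = "together")
  expect_warning(kept <- apply_filters(recs, cfg), "no mapped mate")
  expect_identical(nrow(kept), 1L)
  expect_identical(attr(kept, "n_orphans"), 1L)
})

test_that("secondary always dropped; supplementary dropped by default", {
  recs <- rec_table("c1", c(10, 20, 30), "50M",
                    flag = c(0L, 256L, 2048L))
  expect_identical(nrow(apply_filters(recs, filter_config())), 1L)
  keep_supp <- filter_config(exclude_supplementary = FALSE)
  expect_identical(nrow(apply_filters(recs, keep_supp)), 2L)
})

test_that("filter properties: idempotence, subset ordering, no-op config", {
  set.seed(71)
  for (rep in 1:20) {
    ra <- random_alignments(max_reads = 120L)
    r <- ra$records
    if (nrow(r) == 0L) next
    # make some of them pairs with random pass/fail identities
    half <- seq_len(nrow(r) %/% 2L * 2L)
    r$flag[half] <- rep(c(99L, 147L), length.out = length(half))
    r$qname[half] <- rep(sprintf("p%04d", seq_len(length(half) / 2L)),
                         each = 2L)
    r$nm <- rbinom(nrow(r), pmax(aligned_length(r$cigar), 1L), 0.05)

    cfg_i <- filter_config(min_percent_identity = 0.95,
                           pair_mode = "independent")
    cfg_t <- filter_config(min_percent_identity = 0.95,
                           pair_mode = "together")
    kept_i <- apply_filters(r, cfg_i)
    kept_t <- suppressWarnings(apply_filters(r, cfg_t))

    # idempotence
    expect_identical(apply_filters(kept_i, cfg_i)$qname, kept_i$qname)
    # together-mode kept set is a subset of independent-mode kept set
    expect_true(all(paste(kept_t$qname, kept_t$flag) %in%
                    paste(kept_i$qname, kept_i$flag)))
    # all thresholds disabled keeps every mapped primary record
    expect_identical(nrow(apply_filters(r, filter_config())), nrow(r))
  }
})
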