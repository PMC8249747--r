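test_that("toy-genome generation is reproducible and orientation-complete", {
  a <- generate_toy_genome(2L, seed = 1L)
  b <- generate_toy_genome(2L, seed = 1L)
  expect_identical(a$genes, b$genes)
  expect_identical(as.character(a$seq), as.character(b$seq))

  ann <- generate_toy_genome(20L, seed = 11L, emit_seq = FALSE)
  sp <- compute_spacers(ann)
  expect_true("divergent" %in% sp$orientation)
  expect_true("tandem" %in% sp$orientation)
  expect_error(generate_toy_genome(1L), "n_units")
})

test_that("toy-genome base composition is uniform", {
  # ~100 kb of sequence; chi-square against equal base frequencies
  ann <- generate_toy_genome(48L, seed = 5L)
  counts <- table(strsplit(as.character(ann$seq), "")[[1L]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  expect_gt(sum(counts), 90000)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("fragment library matches the stated length distribution", {
  ann <- generate_toy_genome(20L, seed = 2L, emit_seq = FALSE)
  one <- make_fragment_library(ann, selex_params(library_size = 1L, seed = 1L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$weight, 1.0)

  pool <- make_fragment_library(ann, selex_params(library_size = 10000L,
                                                  seed = 3L))
  lens <- pool$end - pool$start
  expect_lt(abs(mean(lens) - 300), 2)
  expect_true(all(lens >= 100 & lens <= 600))
  expect_lt(abs(sum(pool$weight) - 1), 1e-9)
  expect_true(all(pool$start >= 0 & pool$start < ann$length))
})

test_that("background-only selection is the identity", {
  ann <- generate_toy_genome(5L, seed = 4L, emit_seq = FALSE)
  pool <- make_fragment_library(ann, selex_params(library_size = 500L,
                                                  seed = 4L))
  aff <- affinity_model("bg", data.frame(position = integer(),
                                         strength = numeric()))
  out <- selection_cycle(pool, aff)
  expect_equal(out$weight, pool$weight)
})

test_that("two-fragment pools obey the closed-form enrichment ratio", {
  # fragment 1 covers a site of strength 9 (bind score 10), fragment 2
  # only background (score 1): relative enrichment (10/1)^k
  pool <- data.frame(start = c(1000L, 5000L), end = c(1300L, 5300L),
                     weight = c(0.5, 0.5))
  attr(pool, "genome_len") <- 10000L
  class(pool) <- c("fragment_pool", "data.frame")
  aff <- affinity_model("tf", data.frame(position = 1100L, strength = 9))
  p <- pool
  for (k in 1:3) p <- selection_cycle(p, aff)
  expect_lt(abs(p$weight[1L] / p$weight[2L] - 1000), 1e-9 * 1000)

  # two sites, strengths 9 and 1: ratio (10/2)^k
  aff2 <- affinity_model("tf2", data.frame(position = c(1100L, 5100L),
                                           strength = c(9, 1)))
  p <- pool
  for (k in 1:4) {
    p <- selection_cycle(p, aff2)
    expect_equal(p$weight[1L] / p$weight[2L], 5^k, tolerance = 1e-9)
    expect_lt(abs(sum(p$weight) - 1), 1e-9)
  }
})

test_that("selection handles degenerate and wrapped cases", {
  pool <- data.frame(start = c(100L, 900L), end = c(400L, 1200L),
                     weight = c(0, 0))
  attr(pool, "genome_len") <- 1000L
  aff <- affinity_model("tf", data.frame(position = 150L, strength = 1))
  expect_error(selection_cycle(pool, aff), "zero")

  # wrapped fragment [900, 1200) covers position 50 on a 1000-bp circle
  pool$weight <- c(0.5, 0.5)
  aff_wrap <- affinity_model("tf", data.frame(position = 50L, strength = 9))
  out <- selection_cycle(pool, aff_wrap)
  expect_equal(out$weight[2L] / out$weight[1L], 10)
})

test_that("run_selex is iterated selection with a monotone trace", {
  ann <- generate_toy_genome(10L, seed = 6L, emit_seq = FALSE)
  sp <- compute_spacers(ann)
  site <- eligible_site_spacers(sp, 1L)$site_pos
  aff <- affinity_model("tf", data.frame(position = site, strength = 9))
  pool <- make_fragment_library(ann, selex_params(library_size = 2000L,
                                                  seed = 6L))
  one <- run_selex(pool, aff, 1L)
  expect_equal(one$weight, selection_cycle(pool, aff)$weight)

  out <- run_selex(pool, aff, 6L)
  trace <- attr(out, "trace")
  expect_equal(nrow(trace), 6L)
  expect_true(all(diff(trace$share) >= -1e-12))  # non-decreasing enrichment
  expect_lt(abs(sum(out$weight) - 1), 1e-9)
})

test_that("weak-site fragments vanish relative to strong-site fragments", {
  # strengths 0.5 vs 9 over background 1: per-fragment weight ratio after
  # k cycles is (1.5/10)^k, below 1% of the strong share by cycle 6
  pool <- data.frame(start = c(1000L, 5000L), end = c(1300L, 5300L),
                     weight = c(0.5, 0.5))
  attr(pool, "genome_len") <- 10000L
  aff <- affinity_model("tf", data.frame(position = c(1100L, 5100L),
                                         strength = c(0.5, 9)))
  p <- run_selex(pool, aff, 6L)
  expect_equal(p$weight[1L] / p$weight[2L], (1.5 / 10)^6, tolerance = 1e-9)
  expect_lt(p$weight[1L] / p$weight[2L], 0.01)
})

test_that("selection commutes with permuting the fragment list", {
  ann <- generate_toy_genome(8L, seed = 8L, emit_seq = FALSE)
  pool <- make_fragment_library(ann, selex_params(library_size = 300L,
                                                  seed = 8L))
  aff <- affinity_model("tf", data.frame(
    position = eligible_site_spacers(compute_spacers(ann), 1L)$site_pos,
    strength = 5))
  perm <- sample(nrow(pool))
  shuffled <- pool[perm, ]
  attr(shuffled, "genome_len") <- attr(pool, "genome_len")
  a <- selection_cycle(pool, aff)
  b <- selection_cycle(shuffled, aff)
  expect_equal(b$weight, a$weight[perm])
})

test_that("clone sampling matches its multinomial law", {
  pool <- data.frame(start = 100L, end = 400L, weight = 1)
  attr(pool, "genome_len") <- 1000L
  cl <- sample_clones(pool, 5L, seed = 1L)
  expect_equal(nrow(cl$clones), 5L)
  expect_equal(unique(cl$clones$start), 100L)
  expect_equal(sum(cl$tally$count), 5L)

  pool2 <- data.frame(start = c(100L, 600L), end = c(400L, 900L),
                      weight = c(0.9, 0.1))
  attr(pool2, "genome_len") <- 1000L
  cl2 <- sample_clones(pool2, 10000L, seed = 2L)
  n1 <- sum(cl2$clones$start == 100L)
  sigma <- sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(n1 - 9000), 3 * sigma)
  expect_equal(sum(cl2$tally$count), 10000L)
  expect_equal(clones_at_locus(cl2$clones, 200L, 1000L), n1)
})

test_that("fragment pool BED export parses as standard BED", {
  ann <- generate_toy_genome(5L, seed = 9L, emit_seq = FALSE)
  pool <- make_fragment_library(ann, selex_params(library_size = 50L,
                                                  seed = 9L))
  bed <- tempfile(fileext = ".bed")
  write_pool_bed(pool, ann$genome_id, bed)
  gr <- rtracklayer::import(bed, format = "bed")
  expect_gte(length(gr), 50L)  # wrapped fragments split into two lines
  expect_true(all(GenomicRanges::end(gr) <= ann$length))
})
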