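test_that("GFF3 genes group into units by the operon attribute", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrT 1 5000",
    "chrT\ttoy\tgene\t101\t700\t.\t+\t.\tID=g1",
    "chrT\ttoy\tgene\t801\t1400\t.\t+\t.\tID=g2"), gff)
  ann <- read_annotation(gff)
  expect_equal(nrow(ann$units), 2L)
  expect_equal(ann$length, 5000L)
  expect_equal(ann$genes$start, c(100L, 800L))  # 1-based GFF3 -> 0-based

  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrT 1 5000",
    "chrT\ttoy\tgene\t101\t700\t.\t+\t.\tID=g1;operon=op1",
    "chrT\ttoy\tgene\t801\t1400\t.\t+\t.\tID=g2;operon=op1"), gff)
  ann2 <- read_annotation(gff)
  expect_equal(nrow(ann2$units), 1L)
  expect_setequal(ann2$units$members[[1L]], c("g1", "g2"))
  expect_equal(ann2$units$promoter_pos, 100L)
})

test_that("annotation round-trips through GFF3 + FASTA unchanged", {
  ann <- generate_toy_genome(10L, seed = 42L)
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fasta")
  write_annotation(ann, gff, fa)
  back <- read_annotation(gff, fa)
  expect_equal(back$length, ann$length)
  expect_equal(back$genes[c("gene_id", "start", "end", "strand", "kind",
                            "unit_id")],
               ann$genes[c("gene_id", "start", "end", "strand", "kind",
                           "unit_id")])
  expect_equal(back$units$unit_id, ann$units$unit_id)
  expect_equal(as.character(back$seq), as.character(ann$seq))
  # and a second round trip is byte-identical
  gff2 <- tempfile(fileext = ".gff3")
  write_annotation(back, gff2)
  expect_identical(readLines(gff2), readLines(gff))
})

test_that("annotation validation catches bad input", {
  genes <- data.frame(gene_id = "g1", start = 0L, end = 100L, strand = "+")
  expect_error(genome_annotation("x", -5, genes), "positive")
  expect_error(genome_annotation("x", 50, genes), "outside")
  expect_error(
    genome_annotation("x", 1000,
                      data.frame(gene_id = c("g1", "g1"),
                                 start = c(0L, 200L), end = c(100L, 300L),
                                 strand = "+")),
    "duplicate")
  expect_warning(
    genome_annotation("x", 1000,
                      data.frame(gene_id = c("g1", "g2"),
                                 start = c(0L, 50L), end = c(100L, 300L),
                                 strand = "+")),
    "overlapping")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrT\ttoy\tgene\t101\t700\t.\t+\t.\tID=g1"), gff)
  expect_error(read_annotation(gff), "length")
})

test_that("spacer orientation follows the flanking strands", {
  sp <- compute_spacers(fixture_annotation())
  key <- paste(sp$left_unit, sp$right_unit)
  expect_equal(sp$orientation[key == "u_gA u_gB"], "divergent")
  expect_equal(sp$orientation[key == "u_gB u_gC"], "tandem")
  expect_equal(sp$orientation[key == "u_gC u_gD"], "convergent")
  # wrap spacer uD(-) -> uA(-): tandem, end past the origin
  wrap <- sp[sp$wraps, ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$orientation, "tandem")
  expect_equal(wrap$end - wrap$start, 3000L - 2600L + 0L)
})

test_that("abutting units yield no spacer", {
  ann <- genome_annotation(
    "x", 2000L,
    data.frame(gene_id = c("g1", "g2"), start = c(100L, 500L),
               end = c(500L, 900L), strand = "+"),
    circular = FALSE)
  expect_equal(nrow(compute_spacers(ann)), 0L)
})

test_that("spacers equal a brute-force adjacency scan on random genomes", {
  for (seed in 1:5) {
    ann <- generate_toy_genome(20L, seed = seed, emit_seq = FALSE)
    sp <- compute_spacers(ann)
    br <- brute_spacers(ann)
    expect_equal(nrow(sp), nrow(br))
    expect_equal(sp$left_unit, br$left_unit)
    expect_equal(sp$end - sp$start, br$len)
    expect_equal(sp$orientation, br$orientation)
  }
})

test_that("coordinates are conserved on a linear tiling of units", {
  # units and spacers tile [0, L) exactly
  ann <- genome_annotation(
    "lin", 3000L,
    data.frame(gene_id = c("g1", "g2", "g3"),
               start = c(0L, 1200L, 2400L), end = c(1000L, 2200L, 3000L),
               strand = "+"),
    circular = FALSE)
  sp <- compute_spacers(ann)
  extent <- sum(ann$units$end - ann$units$start) + sum(sp$end - sp$start)
  expect_equal(extent, ann$length)
})

test_that("spacers are invariant under rotation of the circular origin", {
  ann <- generate_toy_genome(15L, seed = 3L, emit_seq = FALSE)
  sp0 <- compute_spacers(ann)
  # rotate so the old origin falls inside a former wrap spacer
  shift <- 100L
  g <- ann$genes
  g$start <- (g$start + shift) %% ann$length
  g$end <- g$start + (ann$genes$end - ann$genes$start)
  stopifnot(all(g$end <= ann$length))  # shift chosen small enough
  ann2 <- genome_annotation(ann$genome_id, ann$length, g, circular = TRUE)
  sp1 <- compute_spacers(ann2)
  expect_equal(sort(sp0$end - sp0$start), sort(sp1$end - sp1$start))
  expect_equal(table(sp0$orientation), table(sp1$orientation))
})

test_that("spacer BED export parses as standard BED", {
  ann <- fixture_annotation()
  sp <- compute_spacers(ann)
  bed <- tempfile(fileext = ".bed")
  write_spacers_bed(sp, ann, bed)
  gr <- rtracklayer::import(bed, format = "bed")
  # wrap spacer split into two lines
  expect_equal(length(gr), nrow(sp) + sum(sp$wraps))
  expect_true(all(GenomicRanges::start(gr) >= 1L))
})
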