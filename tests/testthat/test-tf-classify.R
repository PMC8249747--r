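test_that("target counts map onto the four-group hierarchy", {
  th <- classification_thresholds()
  expect_equal(classify_tf(1, th = th), "ST")
  expect_equal(classify_tf(3, th = th), "ST")
  expect_equal(classify_tf(30, th = th), "local")
  expect_equal(classify_tf(150, th = th), "global")
  expect_equal(classify_tf(200, n_sites = 1000, th = th), "NAP")
  expect_equal(classify_tf(0, th = th), "none")
  # counts in the unclaimed gaps between bands
  expect_equal(classify_tf(7, th = th), "intermediate")
  expect_equal(classify_tf(55, th = th), "intermediate")
  expect_error(classify_tf(-1, th = th), "non-negative")
  expect_error(classification_thresholds(st_max = 20), "st_max")
  # every non-negative count gets exactly one label
  labels <- vapply(0:600, function(n) classify_tf(n, th = th), character(1))
  expect_true(all(labels %in% c("none", "ST", "intermediate", "local",
                                "global", "NAP")))
})

test_that("conditional single-target calls need exactly one ST state", {
  runs <- data.frame(effector_state = c("apo", "AcP"),
                     n_targets = c(1L, 10L), group = c("ST", "local"))
  cc <- classify_conditional(runs)
  expect_true(cc$conditional_st)
  expect_equal(cc$st_state, "apo")

  # effector-bound form as the functional single-target form
  runs2 <- data.frame(effector_state = c("apo", "pHBA"),
                      n_targets = c(50L, 1L),
                      group = c("intermediate", "ST"))
  cc2 <- classify_conditional(runs2)
  expect_true(cc2$conditional_st)
  expect_equal(cc2$st_state, "pHBA")

  both <- data.frame(effector_state = c("a", "b"), n_targets = c(1L, 2L),
                     group = c("ST", "ST"))
  expect_false(classify_conditional(both)$conditional_st)
  single <- data.frame(effector_state = "apo", n_targets = 1L, group = "ST")
  expect_false(classify_conditional(single)$conditional_st)
})

test_that("gene organization splits into adjacent type-A and separated type-B", {
  # lacI-style: TF gene immediately divergent from its target operon
  ann <- genome_annotation(
    "ga", 12000L,
    data.frame(
      gene_id = c("tfg", "t1", "t2", "far"),
      start = c(1000L, 2100L, 3100L, 9000L),
      end = c(1900L, 3000L, 4000L, 9900L),
      strand = c("-", "+", "+", "+"),
      kind = c("TF_gene", "ORF", "ORF", "ORF"),
      unit_id = c("u_tf", "op1", "op1", "u_far")),
    circular = FALSE)
  a <- classify_gene_org("tfg", "op1", ann)
  expect_equal(a$org, "type_A")
  expect_match(a$evidence, "adjacent_to:op1")

  # separated: target unit two units away, distance recorded
  b <- classify_gene_org("tfg", "u_far", ann)
  expect_equal(b$org, "type_B")
  expect_equal(b$evidence, 9000 - 1900)

  # autoregulation: the TF's own unit among the targets
  c_ <- classify_gene_org("tfg", c("u_tf"), ann)
  expect_equal(c_$org, "type_A")
  expect_match(c_$evidence, "member_of")

  expect_error(classify_gene_org("tfg", "nope", ann), "absent")
  expect_error(classify_gene_org("ghost", "op1", ann), "absent")
})

test_that("type-B distance is measured the short way around the circle", {
  ann <- genome_annotation(
    "circ", 10000L,
    data.frame(gene_id = c("tfg", "aa", "bb", "tgt", "cc"),
               start = c(100L, 2000L, 4000L, 9000L, 9850L),
               end = c(900L, 2800L, 4800L, 9800L, 9950L),
               strand = "+"),
    circular = TRUE)
  org <- classify_gene_org("tfg", "u_tgt", ann)
  expect_equal(org$org, "type_B")
  expect_equal(org$evidence, (100 - 9800) %% 10000)  # 300 bp across origin
})

test_that("the packaged single-target TF registry carries the printed lists", {
  reg <- load_registry()
  counted <- reg[reg$in_counts, ]
  expect_equal(nrow(counted), 24L)
  expect_equal(sum(counted$version == 1L), 13L)
  expect_equal(sum(counted$version == 2L), 11L)
  expect_setequal(
    counted$tf_name[counted$version == 2L],
    c("CsqR", "CusR", "HprR", "NorR", "PepA", "PutA", "QseA", "RspR",
      "UvrY", "ZraR", "YqhC"))
  expect_setequal(counted$tf_name[counted$org == "type_B"],
                  c("DecR", "PepA", "RspR", "UvrY"))
  # table-only discrepancy row is present but flagged out of the counts
  expect_true("NemR" %in% reg$tf_name)
  expect_false(reg$in_counts[reg$tf_name == "NemR"])
  expect_false("NemR" %in% load_registry(include_discrepancies = FALSE)$tf_name)
})

test_that("registry report reproduces the printed summary counts", {
  rep <- registry_report()
  expect_equal(rep$total, 24L)
  expect_equal(unname(rep$by_version), c(13L, 11L))
  expect_equal(unname(rep$by_org), c(20L, 4L))
  expect_equal(unname(rep$version_org["2", "type_A"]), 8L)
  expect_equal(unname(rep$version_org["1", "type_A"]), 12L)
})
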