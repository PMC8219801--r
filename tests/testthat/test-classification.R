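test_that("UV-response calls follow the 2-fold definitions with inclusive boundaries", {
  m <- rbind(
    gRep   = c(`0.5` = 0.90, `2.5` = 0.40, `24.5` = 1.0),  # repressed
    gInd   = c(2.50, 1.00, 1.0),                           # induced at 30 min
    gEdge  = c(0.90, 0.50, 1.0),                           # exactly 2-fold
    gBoth  = c(2.10, 0.30, 1.0),                           # conflict
    gNone  = c(1.05, 0.95, 1.0))
  colnames(m) <- c("0.5", "2.5", "24.5")
  rt <- ratio_table_from_matrix(m)
  resp <- call_uv_response(rt)
  got <- setNames(resp$response, resp$gene_id)
  expect_equal(got[["gRep"]], "repressed")
  expect_equal(got[["gInd"]], "induced")
  expect_equal(got[["gEdge"]], "repressed")
  expect_equal(got[["gBoth"]], "excluded")
  expect_equal(resp$reason[resp$gene_id == "gBoth"], "conflict")
  expect_equal(got[["gNone"]], "unchanged")

  # genes excluded upstream are carried through; classes partition the input
  rt2 <- ratio_table_from_matrix(m, excluded = data.frame(
    gene_id = "gZero", condition = "control", reason = "baseline_zero"))
  resp2 <- call_uv_response(rt2)
  expect_setequal(resp2$gene_id, c(rownames(m), "gZero"))
  expect_true(all(table(resp2$gene_id) == 1))

  # a table without the 2.5 h timepoint cannot be classified
  rt3 <- ratio_table_from_matrix(m[, c("0.5", "24.5")])
  expect_error(call_uv_response(rt3), "2.5 h")
})

test_that("kinetics splits repressed genes at detectable 30-min inhibition", {
  m <- rbind(gFast = c(0.40, 0.30, 1), gSlow = c(0.80, 0.45, 1),
             gEdge = c(0.50, 0.45, 1), gNone = c(1.00, 1.00, 1))
  colnames(m) <- c("0.5", "2.5", "24.5")
  resp <- call_kinetics(call_uv_response(ratio_table_from_matrix(m)))
  k <- setNames(resp$kinetics, resp$gene_id)
  expect_equal(k[["gFast"]], "fast")
  expect_equal(k[["gSlow"]], "slow")
  expect_equal(k[["gEdge"]], "fast")                 # inclusive boundary
  expect_equal(k[["gNone"]], "not_applicable")
  expect_error(call_kinetics(resp, genes = "gNone"), "repressed")
})

test_that("dependency calls and band boundaries match the +/-10% definition", {
  mk_rt <- function(ctrl, kd) {
    tp <- c("0.5", "2.5", "24.5")
    m1 <- matrix(rep(c(0.4, 0.3, 0), each = length(ctrl)), ncol = 3,
                 dimnames = list(names(ctrl), tp))
    m1[, 3] <- ctrl
    m2 <- m1
    m2[, 3] <- kd
    a <- ratio_table_from_matrix(m1, "control")
    b <- ratio_table_from_matrix(m2, "kd")
    structure(list(ratios = rbind(a$ratios, b$ratios), excluded = a$excluded,
                   mode = "replicate_mean"), class = "ratio_table")
  }
  genes <- paste0("g", 1:4)
  rt <- mk_rt(setNames(c(1.0, 0.8, 0.5, 0.0), genes),
              setNames(c(0.5, 0.8, 0.6, 0.3), genes))
  dep <- call_dependency(rt, genes, knockdown = "kd")
  expect_equal(dep$dependency, c("stimulated", "independent", "inhibited",
                                 "excluded"))
  expect_equal(dep$relative_recovery[1:3], c(0.5, 1.0, 1.2))
  expect_equal(dep$reason[4], "control_recovery_zero")

  # boundary values land in the outer classes; the bands tile (0, Inf)
  expect_equal(classify_recovery_band(c(0.90, 1.10)),
               c("stimulated", "inhibited"))
  set.seed(42)
  rel <- c(exp(runif(1e4, log(1e-3), log(1e3))), 0.9, 1.1,
           1 - 1e-12, 1 + 1e-12)
  cls <- classify_recovery_band(rel)
  expect_true(all(cls %in% c("stimulated", "independent", "inhibited")))
  expect_equal(cls[rel <= 0.9], rep("stimulated", sum(rel <= 0.9)))
  expect_equal(cls[rel >= 1.1], rep("inhibited", sum(rel >= 1.1)))
  expect_equal(cls[rel > 0.9 & rel < 1.1],
               rep("independent", sum(rel > 0.9 & rel < 1.1)))
})

test_that("classification is invariant to rescaling one gene's values", {
  set.seed(5)
  n <- 50
  vals <- matrix(rlnorm(n * 8, 0, 1), n, 8,
                 dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:8)))
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    condition = rep(c("control", "kd"), each = 4),
    timepoint = rep(c(0, 0.5, 2.5, 24.5), 2), replicate = 1L)
  x <- bru_experiment(vals, samples, state = "scaled_rpkm")
  call_all <- function(x) {
    rt <- relative_to_baseline(x)
    resp <- call_kinetics(call_uv_response(rt))
    dep <- call_dependency(rt, resp$gene_id[resp$response == "repressed"],
                           "kd")
    list(resp = resp[order(resp$gene_id), c("gene_id", "response", "kinetics")],
         dep = dep[, c("gene_id", "dependency")])
  }
  before <- call_all(x)
  x$values["g07", ] <- x$values["g07", ] * 137.5
  x$values["g31", ] <- x$values["g31", ] * 1e-3
  expect_equal(call_all(x), before)
})

test_that("partitions use medians and quartiles recomputed on the analysed set", {
  ann <- gene_annotation(data.frame(
    gene_id = paste0("g", 1:4), chrom = "chr1",
    start = c(0, 1e5, 2e5, 3e5) * 10,
    end = c(0, 1e5, 2e5, 3e5) * 10 + c(2000, 4000, 6000, 8000),
    strand = "+", biotype = c("protein_coding", "lincRNA",
                              "protein_coding", "protein_coding")))
  rpkm <- setNames(c(0.1, 0.4, 0.2, 0.9), paste0("g", 1:4))
  p <- partition_genes(ann, rpkm)
  expect_equal(attr(p, "length_median"), 5000)
  expect_equal(p$length_class, c("short", "short", "long", "long"))
  expect_equal(p$length_quartile, 1:4)
  expect_equal(p$expression_class, c("low", "high", "low", "high"))
  expect_equal(p$biotype_class, c("coding", "noncoding", "coding", "coding"))

  # a gene exactly at the median goes to the lower class
  ann2 <- gene_annotation(data.frame(
    gene_id = paste0("g", 1:3), chrom = "chr1", start = c(0, 1e5, 2e5),
    end = c(0, 1e5, 2e5) + c(2000, 5000, 8000), strand = "+"))
  p2 <- partition_genes(ann2, setNames(c(1, 2, 3), paste0("g", 1:3)))
  expect_equal(p2$length_class[p2$gene_id == "g2"], "short")
  expect_error(partition_genes(ann, setNames(numeric(), character())),
               "empty")
})

test_that("dependency summaries and mean curves reduce correctly", {
  dep <- structure(data.frame(
    gene_id = paste0("g", 1:3), knockdown = "kd",
    recovery_control = 1, recovery_knockdown = c(0.5, 1.0, 0.4),
    relative_recovery = c(0.5, 1.0, 0.4),
    dependency = c("stimulated", "independent", "stimulated"),
    reason = "", stringsAsFactors = FALSE),
    class = c("uv_dependency", "data.frame"))
  s <- summarize_dependency(dep)
  expect_equal(unname(s$fractions),
               c(2 / 3, 1 / 3, 0))
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  s2 <- summarize_dependency(dep[1:2, ])
  expect_equal(unname(s2$fractions), c(0.5, 0.5, 0))

  m <- rbind(g1 = c(0.4, 0.3, 0.9), g2 = c(0.6, 0.5, 1.1))
  colnames(m) <- c("0.5", "2.5", "24.5")
  rt <- ratio_table_from_matrix(m)
  one <- mean_response_curve(rt, "g1", "control")
  expect_equal(one$mean, unname(m["g1", ]))
  expect_equal(one$sd, rep(0, 3))
  both <- mean_response_curve(rt, c("g1", "g2"), "control")
  expect_equal(both$mean[1], 0.5)
  # brute-force recomputation over the raw table
  raw <- rt$ratios
  for (tp in c(0.5, 2.5, 24.5)) {
    v <- raw$ratio[raw$timepoint == tp]
    i <- which(both$timepoint == tp)
    expect_equal(both$mean[i], mean(v))
    expect_equal(both$sd[i], sd(v))
  }
  expect_error(mean_response_curve(rt, character(), "control"), "empty")
})
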