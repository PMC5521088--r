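test_that("noise ratios count pair removals per evidence code", {
  old <- rbind(rec(sprintf("g%02d", 1:10), "GO:0000002", "IEA"),
               rec("h1", "GO:0000003", "IDA"))
  # 2 of the 10 IEA pairs vanish in the newer release
  new <- rbind(rec(sprintf("g%02d", 3:10), "GO:0000002", "IEA"),
               rec("h1", "GO:0000003", "IDA"))
  tab <- noise_ratio_table(old, new, shared = c("GO:0000002", "GO:0000003"))
  expect_equal(tab$ratio[tab$code == "IEA"], 0.2)
  expect_equal(tab$n[tab$code == "IEA"], 10L)
  expect_equal(tab$ratio[tab$code == "IDA"], 0)
  expect_false(tab$observed[tab$code == "TAS"])

  # old subset of new: nothing is noisy
  tab <- noise_ratio_table(old, rbind(old, rec("x", "GO:0000002")),
                           shared = c("GO:0000002", "GO:0000003"))
  expect_true(all(tab$ratio == 0))

  # a pair that only changes evidence code is not noisy
  old2 <- rec("g1", "GO:0000002", "IEA")
  new2 <- rec("g1", "GO:0000002", "IDA")
  tab <- noise_ratio_table(old2, new2, shared = "GO:0000002")
  expect_equal(tab$ratio[tab$code == "IEA"], 0)
})

test_that("ratio averaging over release pairs", {
  mk <- function(r) data.frame(code = GO_EVIDENCE_CODES,
                               ratio = ifelse(GO_EVIDENCE_CODES == "IEA",
                                              r, 0),
                               observed = GO_EVIDENCE_CODES == "IEA")
  tabs <- list(mk(0.0), mk(0.1), mk(0.3))
  expect_equal(average_ratios(tabs, l = 1)$r_tilde[
    GO_EVIDENCE_CODES == "IEA"], 0.3)
  expect_equal(average_ratios(tabs, l = 2)$r_tilde[
    GO_EVIDENCE_CODES == "IEA"], 0.2)
  expect_equal(average_ratios(list(mk(0.0), mk(0.3), mk(0.3)), l = 3)$
                 r_tilde[GO_EVIDENCE_CODES == "IEA"], 0.2)
  expect_error(average_ratios(tabs, l = 4), "between")
})

test_that("code weights split at the mean ratio, ties down-weighted", {
  rt <- data.frame(code = c("IEA", "IDA"), r_tilde = c(0.2, 0.0),
                   observed = c(TRUE, TRUE))
  w <- evidence_weights(rt, theta = 0.5)
  expect_equal(attr(w, "tau"), 0.1)
  expect_equal(w$weight[w$code == "IEA"], 0.5)
  expect_equal(w$weight[w$code == "IDA"], 1)

  # all ratios equal: everything sits at tau and takes theta
  rt2 <- data.frame(code = c("IEA", "IDA", "TAS"), r_tilde = rep(0.1, 3),
                    observed = TRUE)
  expect_true(all(evidence_weights(rt2, 0.5)$weight == 0.5))

  # single observed code: tau equals its ratio, weight theta
  rt3 <- data.frame(code = "IEA", r_tilde = 0.4, observed = TRUE)
  expect_equal(evidence_weights(rt3, 0.25)$weight, 0.25)

  expect_error(evidence_weights(rt, theta = 1), "between 0 and 1")
  expect_error(evidence_weights(rt, theta = 0), "between 0 and 1")
})

test_that("direct weighting takes the maximal weight over codes", {
  dag <- diamond_dag()
  r <- rbind(rec("g1", "GO:0000004", "IEA"),
             rec("g1", "GO:0000004", "IDA"),
             rec("g2", "GO:0000004", "IEA"))
  A <- annotation_matrix(r, term_order = dag$terms)
  w <- evidence_weights(
    data.frame(code = c("IEA", "IDA"), r_tilde = c(0.3, 0.0),
               observed = TRUE), theta = 0.5)
  W <- weight_annotations(A, w)
  expect_equal(W$M["g1", "GO:0000004"], 1)    # max(theta, 1)
  expect_equal(W$M["g2", "GO:0000004"], 0.5)  # single down-weighted code
  expect_equal(W$M["g1", "GO:0000002"], 0)    # zero entries stay zero
})

test_that("weight propagation takes the max over contributing directs", {
  dag <- diamond_dag()
  w <- evidence_weights(
    data.frame(code = c("IEA", "IDA"), r_tilde = c(0.3, 0.0),
               observed = TRUE), theta = 0.5)

  # single direct at the leaf: the whole ancestor chain takes its weight
  A1 <- annotation_matrix(rec("g1", "GO:0000004", "IEA"),
                          term_order = dag$terms)
  P1 <- propagate_weights(weight_annotations(A1, w), dag)
  expect_equal(unname(P1$M["g1", c("GO:0000002", "GO:0000003",
                                   "GO:0000004")]),
               c(0.5, 0.5, 0.5))

  # a direct ancestor with weight 1 dominates the propagated 0.5
  A2 <- annotation_matrix(rbind(rec("g1", "GO:0000004", "IEA"),
                                rec("g1", "GO:0000002", "IDA")),
                          term_order = dag$terms)
  P2 <- propagate_weights(weight_annotations(A2, w), dag)
  expect_equal(P2$M["g1", "GO:0000002"], 1)
  expect_equal(P2$M["g1", "GO:0000004"], 0.5)

  # diamond: two directs (0.5 and 1) sharing an ancestor -> ancestor 1
  A3 <- annotation_matrix(rbind(rec("g1", "GO:0000002", "IEA"),
                                rec("g1", "GO:0000003", "IDA")),
                          term_order = dag$terms)
  P3 <- propagate_weights(weight_annotations(A3, w), dag)
  # both directs propagate only to the (dropped) root; weights stay put
  expect_equal(P3$M["g1", "GO:0000002"], 0.5)
  expect_equal(P3$M["g1", "GO:0000003"], 1)
})

test_that("weighted propagation preserves support and closes monotonely", {
  for (seed in c(3, 17)) {
    fx <- random_fixture(seed)
    A <- annotation_matrix(fx$records, term_order = fx$dag$terms)
    w <- evidence_weights(data.frame(
      code = c("IEA", "IDA", "TAS", "IMP"),
      r_tilde = c(0.3, 0.0, 0.1, 0.05), observed = TRUE), theta = 0.5)
    Wd <- weight_annotations(A, w)
    P <- propagate_weights(Wd, fx$dag)
    B <- propagate_annotations(A, fx$dag)
    # support preservation
    expect_equal(as.matrix(P$M != 0), as.matrix(B$M != 0))
    # A_ec(i, s) >= A^d_ec(i, t) for every annotated ancestor s of t
    tri <- Matrix::summary(Wd$M)
    for (k in seq_len(nrow(tri))) {
      t <- Wd$terms[[tri$j[[k]]]]
      up <- intersect(go_ancestors(fx$dag, t), P$terms)
      if (length(up)) {
        expect_true(all(P$M[tri$i[[k]], up] >= tri$x[[k]]))
      }
    }
  }
})

test_that("injected per-code removal rates are recovered within 3 sigma", {
  cfg <- sim_config(n_terms = 60L, n_layers = 3L, n_genes = 900L,
                    n_clusters = 3L,
                    directs_per_gene = 8L, profile_noise = 0,
                    code_mix = c(IEA = 1, IDA = 1, TAS = 1) / 3,
                    removal_rates = c(IEA = 0.2, IDA = 0.05, TAS = 0.1))
  dag <- generate_dag(cfg, seed = 5)
  ann <- generate_annotations(dag, cfg, seed = 6)
  pair <- make_release_pair(ann$records, cfg, seed = 7)
  tab <- noise_ratio_table(pair$historical, pair$recent,
                           shared = dag$terms)
  for (code in names(cfg$removal_rates)) {
    p <- cfg$removal_rates[[code]]
    n <- tab$n[tab$code == code]
    expect_gte(n, 2000L)
    expect_lt(abs(tab$ratio[tab$code == code] - p),
              3 * sqrt(p * (1 - p) / n))
  }
})
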