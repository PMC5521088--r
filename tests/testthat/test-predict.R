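test_that("score fusion is the stated affine combination", {
  v_sr <- matrix(c(0.5, 0.2), 1, 2)
  a_ec <- matrix(c(1, 0.5), 1, 2)
  expect_equal(unname(fuse_scores(v_sr, a_ec, 0.2)),
               matrix(c(0.2 * 0.5 + 0.8 * 1, 0.2 * 0.2 + 0.8 * 0.5), 1, 2))
  expect_equal(fuse_scores(v_sr, a_ec, 0), a_ec)
  expect_equal(fuse_scores(v_sr, a_ec, 1), v_sr)
  expect_error(fuse_scores(v_sr, a_ec, 1.2), "0, 1")
  expect_error(fuse_scores(v_sr, a_ec[, 1, drop = FALSE], 0.5),
               "mismatch")
})

make_toy <- function() {
  A <- matrix(c(1, 1, 1, 0,
                1, 0, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              paste0("GO:000000", 2:5)))
  V <- matrix(c(0.9, 0.1, 0.5, 0.0,
                0.3, 0.0, 0.8, 0.2), 2, 4, byrow = TRUE,
              dimnames = dimnames(A))
  list(A = A, V = V)
}

test_that("q-selection ranks annotated terms by ascending fused score", {
  toy <- make_toy()
  expect_equal(nrow(select_noisy(toy$V, toy$A, 0)), 0L)

  sel <- select_noisy(toy$V, toy$A, 1)
  expect_equal(sel$term[sel$gene == "g1"], "GO:0000003") # argmin 0.1
  expect_equal(sel$term[sel$gene == "g2"], "GO:0000005") # argmin 0.2

  # q = annotated count selects everything; larger q is clamped
  sel_all <- select_noisy(toy$V, toy$A, 3)
  expect_equal(sum(sel_all$gene == "g1"), 3L)
  expect_equal(select_noisy(toy$V, toy$A, 99), sel_all)

  # per-gene q map; absent genes get 0
  sel <- select_noisy(toy$V, toy$A, c(g2 = 2L))
  expect_setequal(sel$gene, "g2")
  expect_equal(sel$term, c("GO:0000005", "GO:0000002"))

  # ties break lexicographically by term id
  Vt <- toy$V; Vt["g1", ] <- 0.5
  sel <- select_noisy(Vt, toy$A, 1)
  expect_equal(sel$term[sel$gene == "g1"], "GO:0000002")
})

test_that("selection is invariant to input ordering and V-monotone", {
  toy <- make_toy()
  perm_g <- c(2, 1); perm_t <- c(3, 1, 4, 2)
  sel <- select_noisy(toy$V, toy$A, 2)
  sel_p <- select_noisy(toy$V[perm_g, perm_t], toy$A[perm_g, perm_t], 2)
  key <- function(s) sort(paste(s$gene, s$term))
  expect_equal(key(sel), key(sel_p))

  # lowering a selected term's score never evicts it
  V2 <- toy$V; V2["g1", "GO:0000003"] <- 0.01
  sel2 <- select_noisy(V2, toy$A, 2)
  expect_true("GO:0000003" %in% sel2$term[sel2$gene == "g1"])
})

test_that("descendant expansion is closed and idempotent", {
  dag <- diamond_dag()
  A <- annotation_matrix(rec("g1", c("GO:0000002", "GO:0000004")),
                         term_order = dag$terms)
  P <- propagate_annotations(A, dag)
  V <- matrix(0.1, 1, 3, dimnames = list("g1", P$terms))

  sel <- structure(
    data.frame(gene = "g1", term = "GO:0000002", score = 0.1, rank = 1L,
               inherited = FALSE),
    class = c("noise_prediction", "data.frame"))
  ex <- expand_descendants(sel, P, dag, V)
  expect_setequal(ex$term, c("GO:0000002", "GO:0000004"))
  expect_true(ex$inherited[ex$term == "GO:0000004"])
  expect_identical(expand_descendants(ex, P, dag, V), ex)

  # a selection with no annotated descendants is unchanged
  sel4 <- structure(
    data.frame(gene = "g1", term = "GO:0000004", score = 0.1, rank = 1L,
               inherited = FALSE),
    class = c("noise_prediction", "data.frame"))
  expect_identical(expand_descendants(sel4, P, dag, V), sel4)
})

test_that("threshold mode flags scores under the cutoff", {
  dag <- diamond_dag()
  A <- annotation_matrix(rbind(rec("g1", "GO:0000002"),
                               rec("g1", "GO:0000003")),
                         term_order = dag$terms)
  P <- propagate_annotations(A, dag)
  # alpha = 0.2, theta = 0.5: A_ec 0.5 and V_SR 0.2 fuse to 0.44 < 0.45
  V <- matrix(c(0.2 * 0.2 + 0.8 * 0.5, 0.2 * 0.9 + 0.8 * 1, 0), 1, 3,
              dimnames = list("g1", P$terms))
  got <- threshold_noisy(V, P, dag, v_cut = 0.45)
  expect_equal(got$term[!got$inherited], "GO:0000002")
  # a full-weight annotation scores >= 0.8 and is never flagged at 0.45
  expect_false("GO:0000003" %in% got$term)
  # empty matrix: empty prediction
  empty <- threshold_noisy(V * 0 + 1, P, dag, v_cut = 0.45)
  expect_equal(nrow(empty), 0L)
})

test_that("random baseline is seeded, uniform, and exhaustive at full q", {
  dag <- diamond_dag()
  genes <- sprintf("g%05d", 1:8000)
  A <- annotation_matrix(
    rec(rep(genes, each = 2),
        rep(c("GO:0000002", "GO:0000003"), length(genes))),
    term_order = dag$terms)
  P <- propagate_annotations(A, dag)

  b1 <- baseline_random(P, dag, 1, seed = 9)
  b2 <- baseline_random(P, dag, 1, seed = 9)
  expect_identical(b1, b2)
  # uniform marginal over the two annotated terms
  frac <- mean(b1$term == "GO:0000002")
  expect_lt(abs(frac - 0.5), 0.02)

  ball <- baseline_random(P, dag, 2, seed = 1)
  expect_equal(nrow(ball), 2L * length(genes))
})

test_that("lowest-frequency baseline picks rare terms first", {
  A <- matrix(c(1, 1, 1,
                1, 0, 1,
                1, 0, 1,
                1, 0, 0,
                1, 0, 0), 5, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:5),
                              c("GO:0000002", "GO:0000003", "GO:0000004")))
  dag <- diamond_dag()
  # column sums: 5, 1, 3 -> g1 with q=1 takes the frequency-1 term
  # (its annotated descendant GO:0000004 is then flagged as inherited)
  b <- baseline_lf(A, dag, c(g1 = 1L), seed = 2)
  expect_equal(b$term[!b$inherited], "GO:0000003")
  expect_equal(b$term[b$inherited], "GO:0000004")
  b2 <- baseline_lf(A, dag, c(g1 = 2L), seed = 2)
  expect_setequal(b2$term[!b2$inherited], c("GO:0000003", "GO:0000004"))

  # all-equal frequencies: seeded random, reproducible
  Aeq <- A; Aeq[] <- 1
  t1 <- baseline_lf(Aeq, dag, 1, seed = 3)
  expect_identical(t1, baseline_lf(Aeq, dag, 1, seed = 3))
})

test_that("fitted model special cases reduce to the EC and SR rankings", {
  fx <- random_fixture(31, n_genes = 12L)
  pair <- make_release_pair(fx$records, fx$cfg, seed = 32)
  fit0 <- suppressWarnings(
    goanoise(pair$historical, fx$dag, alpha = 0,
             history = list(list(old = pair$historical,
                                 new = pair$recent))))
  expect_equal(fit0$V, as.matrix(fit0$A_ec$M), ignore_attr = TRUE)
  fit1 <- suppressWarnings(
    goanoise(pair$historical, fx$dag, alpha = 1,
             history = list(list(old = pair$historical,
                                 new = pair$recent))))
  expect_equal(fit1$V, fit1$V_sr)
  # EC ranking: q-selection equals picking the lowest evidence weights
  sel0 <- select_noisy(fit0$V, fit0$A, 2)
  sel_ec <- select_noisy(as.matrix(fit0$A_ec$M), fit0$A, 2)
  expect_identical(sel0[c("gene", "term")], sel_ec[c("gene", "term")])
})

test_that("model object methods expose the fit", {
  fx <- random_fixture(41, n_genes = 10L)
  pair <- make_release_pair(fx$records, fx$cfg, seed = 42)
  fit <- suppressWarnings(
    goanoise(pair$historical, fx$dag,
             history = list(list(old = pair$historical,
                                 new = pair$recent))))
  expect_s3_class(fit, "goanoise")
  expect_output(print(fit), "genes")
  expect_output(print(summary(fit)), "evidence codes")
  expect_equal(dim(coef(fit)), rep(length(fit$A$genes), 2))

  pr <- predict(fit, mode = "q", q = 1)
  expect_s3_class(pr, "noise_prediction")
  expect_true(all(table(pr$gene[!pr$inherited]) == 1))
  rk <- rank_annotations(fit, fit$A$genes[[1]])
  expect_false(is.unsorted(rk$score))
  expect_error(predict(fit, mode = "q"), "required")
})
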