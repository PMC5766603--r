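test_that("site matching finds chemically sensible reaction centers", {
  cc <- toy_fixture()
  rid <- cc$rules1$info$rule_id[1]
  # salicylate: a single center anchored at the carboxyl carbon
  sites <- match_sites(cc$rules1, rid, cc$toy$mols$sal)
  expect_equal(nrow(sites), 1L)
  sal <- cc$toy$mols$sal
  carboxyl_c <- 2L  # OC(=O)... second atom is the carboxyl carbon
  expect_true(carboxyl_c %in% sites$atoms[[1]])
  # 2hipa: two symmetric carboxyls, two centers
  s2 <- match_sites(cc$rules1, rid, cc$toy$mols$`2hipa`)
  expect_equal(nrow(s2), 2L)
  # phenol has no carboxyl: empty result, not an error
  expect_equal(nrow(match_sites(cc$rules1, rid, cc$toy$mols$phnl)), 0L)
})

test_that("decarboxylation applied to salicylate yields phenol plus CO2", {
  cc <- toy_fixture()
  rid <- cc$rules1$info$rule_id[1]
  sites <- match_sites(cc$rules1, rid, cc$toy$mols$sal)
  app <- apply_rule(cc$rules1, rid, cc$toy$mols$sal, center = sites$atoms[[1]])
  expect_equal(app$status, "ok")
  expect_true(app$residual_ok)
  prods <- app$products[[1]]
  expect_setequal(vapply(prods, molecular_formula, character(1)),
                  c("C6H6O", "CO2"))
  # the phenol candidate is label-identical to authentic phenol at size 3
  fps <- vapply(prods, label_fingerprint, character(1), 3, cc$reg)
  expect_true(label_fingerprint(cc$toy$mols$phnl, 3, cc$reg) %in% fps)
  # elemental audit: products match the substrate atom for atom
  lhs <- tibble::deframe(element_counts(cc$toy$mols$sal))
  rhs <- Reduce(`+`, lapply(prods, function(p) {
    v <- tibble::deframe(element_counts(p))
    out <- stats::setNames(numeric(length(lhs)), names(lhs))
    out[names(v)] <- v
    out
  }))
  expect_equal(rhs, lhs[names(rhs)])
})

test_that("the reversed rule rebuilds a salicylate-signature structure", {
  cc <- toy_fixture()
  rid <- cc$rules1$info$rule_id[1]
  subs <- list(cc$toy$mols$phnl, cc$toy$mols$co2)
  sites <- match_sites(cc$rules1, rid, subs, direction = "reverse")
  expect_gt(nrow(sites), 0L)
  sal_fp <- label_fingerprint(cc$toy$mols$sal, 3, cc$reg)
  recovered <- FALSE
  for (i in seq_len(nrow(sites))) {
    app <- apply_rule(cc$rules1, rid, subs, center = sites$atoms[[i]],
                      direction = "reverse")
    for (ps in app$products) {
      fps <- vapply(ps, label_fingerprint, character(1), 3, cc$reg)
      if (sal_fp %in% fps) recovered <- TRUE
    }
    if (recovered) break
  }
  expect_true(recovered)
})

test_that("identity application and unmatchable centers behave as documented", {
  cc <- toy_fixture()
  # an identity rule (empty change map) returns the substrates unchanged
  rs <- cc$rules1
  rs$rules <- rs$rules[0, ]
  rs$info <- tibble::tibble(rule_id = "Rid", reversible = TRUE,
                            member_reactions = list(character(0)),
                            pathways = list(character(0)),
                            organisms = list(character(0)))
  app <- apply_rule(rs, "Rid", cc$toy$mols$sal)
  expect_equal(app$status, "ok")
  expect_equal(length(app$products[[1]]), 1L)
  expect_equal(label_fingerprint(app$products[[1]][[1]], 3, cc$reg),
               label_fingerprint(cc$toy$mols$sal, 3, cc$reg))
  # a center where the chemistry cannot be realized is flagged, not an error
  rid <- cc$rules1$info$rule_id[1]
  app2 <- apply_rule(cc$rules1, rid, cc$toy$mols$sal,
                     center = c(1L, 2L), max_edits = 1L)
  expect_equal(app2$status, "unrealizable at this center")
})

test_that("round trip: a rule then its reverse restores the original labels", {
  cc <- toy_fixture()
  rid <- cc$rules1$info$rule_id[1]
  sal <- cc$toy$mols$sal
  fwd <- apply_rule(cc$rules1, rid, sal,
                    center = match_sites(cc$rules1, rid, sal)$atoms[[1]])
  prods <- fwd$products[[1]]
  back_sites <- match_sites(cc$rules1, rid, prods, direction = "reverse")
  orig_fp <- label_fingerprint(sal, 3, cc$reg)
  restored <- FALSE
  for (i in seq_len(nrow(back_sites))) {
    app <- apply_rule(cc$rules1, rid, prods, center = back_sites$atoms[[i]],
                      direction = "reverse")
    for (ps in app$products) {
      if (length(ps) == 1L &&
          label_fingerprint(ps[[1]], 3, cc$reg) == orig_fp) restored <- TRUE
    }
    if (restored) break
  }
  expect_true(restored)
})
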