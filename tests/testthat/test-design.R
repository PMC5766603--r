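test_that("the toy model has the expected shape at moiety size 1", {
  cc <- toy_fixture()
  model <- build_design_model(toy_design(lambda = 1), cc$toy$db, cc$rules1,
                              cc$sigs1, cc$toy$thermo)
  expect_equal(sum(startsWith(model$con$label, "component|")), 4L)
  moieties1 <- sort(unique(cc$sigs1$moiety))
  expect_equal(sum(startsWith(model$con$label, "moiety|")), length(moieties1))
  expect_equal(sum(model$steps$type == "known"), 2L)
  expect_equal(sum(model$steps$type == "rule"), 1L)
  expect_true("thermo" %in% model$con$label)
})

test_that("mixing moiety sizes between rules and design is refused", {
  cc <- toy_fixture()
  expect_error(
    build_design_model(toy_design(lambda = 2), cc$toy$db, cc$rules1,
                       cc$sigs2, cc$toy$thermo),
    "never mixed")
  expect_error(
    build_design_model(toy_design(lambda = 2), cc$toy$db, cc$rules2,
                       cc$sigs1, cc$toy$thermo),
    "lambda")
})

test_that("toy enumeration returns the four blended designs, all validated", {
  cc <- toy_pathways()
  ps <- cc$ps
  expect_equal(nrow(ps), 4L)
  expect_equal(attr(ps, "status"), "ok")
  expect_setequal(ps$steps, c("2HIPD+ SLD+", "2HIPD+ R2+", "R1+ R2+", "R1+ SLD+"))
  expect_true(all(ps$valid))
  expect_true(all(ps$objective == 2))
  # one solution uses both known reactions and zero rules
  known_only <- ps[ps$steps == "2HIPD+ SLD+", ]
  expect_equal(known_only$rule_count, 0L)
  # solutions arrive in non-worsening objective order, ties lexicographic
  expect_equal(ps$steps, sort(ps$steps))
})

test_that("the worked known-plus-rule solution shows the expected imbalances", {
  cc <- toy_pathways()
  s <- cc$ps$solution[[match("2HIPD+ R2+", cc$ps$steps)]]
  expect_equal(s$vimb[["2hipa"]], -1L)
  expect_equal(s$vimb[["sal"]], 1L)
  expect_equal(s$vimb[["co2"]], 1L)
  rep <- validate_solution(s, cc$toy_model)
  expect_true(all(rep$ok))
})

test_that("validation pinpoints a perturbed solution and flags empty designs", {
  cc <- toy_pathways()
  s <- cc$ps$solution[[1]]
  s_bad <- s
  s_bad$vimb[["sal"]] <- s_bad$vimb[["sal"]] + 1L
  rep <- validate_solution(s_bad, cc$toy_model)
  bad_rows <- rep[!rep$ok, ]
  expect_true(any(bad_rows$check == "component"))
  # exactly one component row broken (sal), plus its induced moiety rows
  expect_equal(sum(bad_rows$check == "component"), 1L)
  # an all-zero solution validates but is flagged
  s0 <- s
  s0$fluxes$flux <- 0L; s0$fluxes$direction <- NA_character_
  s0$vimb[] <- 0L; s0$vex[] <- 0L; s0$step_count <- 0L; s0$rule_count <- 0L
  rep0 <- validate_solution(s0, cc$toy_model)
  expect_true("empty design" %in% attr(rep0, "flags"))
})

test_that("net conversion normalizes to the target and is elementally balanced", {
  cc <- toy_pathways()
  for (i in seq_len(nrow(cc$ps))) {
    conv <- net_conversion(cc$ps$solution[[i]], cc$toy_model)
    expect_equal(conv$coef[conv$metabolite == "phnl"], 1)
    expect_equal(conv$coef[conv$metabolite == "2hipa"], -1)
    expect_equal(conv$coef[conv$metabolite == "co2"], 2)
    # element audit with independent atom counting
    vecs <- lapply(conv$metabolite, function(m) {
      tibble::deframe(element_counts(toy_fixture()$toy$mols[[m]]))
    })
    els <- unique(unlist(lapply(vecs, names)))
    for (e in els) {
      tot <- sum(vapply(seq_along(vecs), function(k) {
        v <- vecs[[k]][e]
        conv$coef[k] * (if (is.na(v)) 0 else v)
      }, numeric(1)))
      expect_equal(tot, 0)
    }
  }
  # zero target flux is an explicit error
  s0 <- cc$ps$solution[[1]]
  s0$vex[["phnl"]] <- 0L
  expect_error(net_conversion(s0, cc$toy_model), "target")
})

test_that("an empty rule set reduces the search to known reactions only", {
  cc <- toy_fixture()
  model <- build_design_model(toy_design(lambda = 2), cc$toy$db, NULL,
                              cc$sigs2, cc$toy$thermo)
  ps <- solve_pathways(model, k = 10)
  expect_equal(ps$steps, "2HIPD+ SLD+")
})

test_that("a linear known chain of length L yields min_total_steps exactly L", {
  for (L in c(1L, 2L, 4L)) {
    net <- planted_network(n_mets = L + 4, n_rxns = L, route_len = L,
                           seed = 100 + L)
    reg <- prime_registry()
    sigs <- signature_index(net$mols, 1, reg)
    model <- build_design_model(planted_design(net), net$db, NULL, sigs,
                                net$thermo)
    ps <- solve_pathways(model, k = 1)
    expect_equal(ps$step_count[1], L)
  }
})

test_that("tidy, glance and autoplot summarize a pathway set", {
  cc <- toy_pathways()
  td <- tidy(cc$ps)
  expect_true(all(c("solution", "step", "flux", "direction") %in% names(td)))
  expect_equal(nrow(td), 8L)  # 4 solutions x 2 active steps
  gl <- glance(cc$ps)
  expect_equal(gl$n_solutions, 4L)
  expect_true(gl$all_valid)
  p <- autoplot(cc$ps)
  expect_s3_class(p, "ggplot")
})

test_that("infeasible designs return an empty set with a certificate", {
  cc <- toy_fixture()
  # demanding export of the target with no usable step: ban CO2 exchange
  prob <- toy_design(lambda = 2, banned_exchanges = "co2")
  model <- build_design_model(prob, cc$toy$db, cc$rules2, cc$sigs2,
                              cc$toy$thermo)
  ps <- solve_pathways(model, k = 5)
  expect_equal(nrow(ps), 0L)
  expect_equal(attr(ps, "status"), "infeasible")
})

test_that("profit maximization needs prices and finite bounds", {
  cc <- toy_fixture()
  expect_error(
    build_design_model(toy_design(lambda = 2, objective = "max_profit"),
                       cc$toy$db, cc$rules2, cc$sigs2, cc$toy$thermo),
    "prices")
  prob <- toy_design(lambda = 2, objective = "max_profit",
                     prices = c(phnl = 5, `2hipa` = 1, co2 = 0))
  model <- build_design_model(prob, cc$toy$db, cc$rules2, cc$sigs2,
                              cc$toy$thermo)
  ps <- solve_pathways(model, k = 2)
  # profit of the unit conversion: 5*1 - 1*1 = 4, objective is -profit
  expect_equal(ps$objective[1], -4)
})
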