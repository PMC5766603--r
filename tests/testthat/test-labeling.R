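test_that("canonical labels separate and merge atoms as the moiety size demands", {
  cc <- toy_fixture()
  co2 <- cc$toy$mols$co2
  l1 <- atom_labels(co2, 1, cc$reg)
  # two equivalent oxygens, one distinct carbon
  expect_equal(length(unique(l1$prime)), 2L)
  expect_equal(sort(table(l1$prime)), sort(c(1L, 2L)), ignore_attr = TRUE)

  hipa <- cc$toy$mols$`2hipa`
  l2 <- atom_labels(hipa, 2, cc$reg)
  carboxyl <- which(hipa$atoms$element == "C" &
                      vapply(seq_len(nrow(hipa$atoms)), function(a) {
                        b <- hipa$bonds
                        sum((b$from == a | b$to == a) & b$order == 2) == 1
                      }, logical(1)))
  # the two carboxyl carbons sit in symmetric environments: same label
  expect_length(carboxyl, 2L)
  expect_equal(l2$prime[carboxyl[1]], l2$prime[carboxyl[2]])
  # the hydroxyl-bearing ring carbon is distinct from every other carbon
  oh_ring <- 12L  # the closing c1O atom in OC(=O)c1cccc(C(O)=O)c1O
  stopifnot(hipa$atoms$element[oh_ring] == "C")
  expect_false(l2$prime[oh_ring] %in% l2$prime[-oh_ring])
})

test_that("label multisets are invariant under atom permutations", {
  cc <- toy_fixture()
  set.seed(7)
  for (mol in cc$toy$mols) {
    for (lam in 1:3) {
      ref <- sort(atom_labels(mol, lam, cc$reg)$prime)
      for (rep in 1:25) {
        perm <- sample(nrow(mol$atoms))
        got <- sort(atom_labels(permute_molecule(mol, perm), lam, cc$reg)$prime)
        expect_equal(got, ref)
      }
    }
  }
})

test_that("lambda outside 1..3 is rejected", {
  cc <- toy_fixture()
  expect_error(atom_labels(cc$toy$mols$co2, 0, cc$reg), "lambda")
  expect_error(atom_labels(cc$toy$mols$co2, 4, cc$reg), "lambda")
})

test_that("signatures count one moiety per atom and are additive over components", {
  cc <- toy_fixture()
  for (mol in cc$toy$mols) {
    for (lam in 1:3) {
      sig <- mol_signature(mol, lam, cc$reg)
      expect_true(all(sig$count > 0L))
      expect_equal(sum(sig$count), nrow(mol$atoms))
    }
  }
  # signature(union(A, B)) = signature(A) + signature(B)
  set.seed(11)
  ids <- names(cc$toy$mols)
  for (rep in 1:10) {
    pair <- sample(ids, 2)
    a <- cc$toy$mols[[pair[1]]]; b <- cc$toy$mols[[pair[2]]]
    u <- parse_structure(paste0(a$source, ".", b$source), id = "u")
    su <- mol_signature(u, 2, cc$reg)
    sa <- mol_signature(a, 2, cc$reg); sb <- mol_signature(b, 2, cc$reg)
    added <- dplyr::full_join(sa[, c("moiety", "count")],
                              sb[, c("moiety", "count")], by = "moiety") |>
      dplyr::transmute(moiety,
                       count = dplyr::coalesce(count.x, 0L) +
                         dplyr::coalesce(count.y, 0L)) |>
      dplyr::arrange(moiety)
    expect_equal(sig_string(su), sig_string(added))
  }
})

test_that("rule derivation matches stoichiometry and rejects imbalance", {
  cc <- toy_fixture()
  sigs <- cc$sigs1
  # identity conversion (two ids, same structure): empty change map
  twin_sigs <- signature_index(list(salA = cc$toy$mols$sal,
                                    salB = cc$toy$mols$sal), 1, cc$reg)
  ident <- derive_rule(c(salA = -1, salB = 1), twin_sigs, cc$reg)
  expect_equal(nrow(ident), 0L)
  # reversing a reaction negates the change map
  fwd <- derive_rule(c(sal = -1, phnl = 1, co2 = 1), sigs, cc$reg)
  rev <- derive_rule(c(sal = 1, phnl = -1, co2 = -1), sigs, cc$reg)
  expect_equal(fwd$moiety, rev$moiety)
  expect_equal(fwd$change, -rev$change)
  # missing signature and elemental imbalance are explicit errors
  expect_error(derive_rule(c(nothere = -1, sal = 1), sigs, cc$reg), "nothere")
  expect_error(derive_rule(c(sal = -1, phnl = 1), sigs, cc$reg), "unbalanced")
})

test_that("toy rule extraction reproduces the published counts and merges", {
  cc <- toy_fixture()
  expect_equal(n_rules(cc$rules1), 1L)
  expect_equal(n_rules(cc$rules2), 2L)
  # at size 1 both decarboxylases collapse onto one rule
  expect_setequal(cc$rules1$info$member_reactions[[1]], c("2HIPD", "SLD"))
  # at size 2 each reaction keeps its own rule
  expect_equal(sort(unlist(cc$rules2$info$member_reactions)), c("2HIPD", "SLD"))
  expect_equal(nrow(cc$rules2$map), 2L)
})

test_that("rule extraction is order independent and dedup is idempotent", {
  cc <- toy_fixture()
  toy <- cc$toy
  # shuffled database: same fingerprint set, same ids
  st <- toy$db$stoich[rev(seq_len(nrow(toy$db$stoich))), ]
  db_shuf <- reaction_db(st)
  rs_shuf <- extract_rules(db_shuf, toy$mols, 2, cc$reg)
  expect_equal(rs_shuf$rules[, c("rule_id", "moiety", "change")],
               cc$rules2$rules[, c("rule_id", "moiety", "change")])
  # duplicating every reaction under new ids does not add rules
  st2 <- dplyr::bind_rows(toy$db$stoich,
                          dplyr::mutate(toy$db$stoich,
                                        reaction = paste0(reaction, "_copy")))
  rs_dup <- extract_rules(reaction_db(st2), toy$mols, 2, cc$reg)
  expect_equal(n_rules(rs_dup), n_rules(cc$rules2))
  expect_equal(nrow(rs_dup$map), 4L)
})

test_that("every extracted rule is elementally balanced, failures are collected", {
  cc <- toy_fixture()
  for (rs in list(cc$rules1, cc$rules2)) {
    bal <- rule_element_balance(rs)
    expect_true(all(bal$residual == 0L))
  }
  # a corrupt reaction is rejected with a reason, the rest proceed
  st <- dplyr::bind_rows(cc$toy$db$stoich,
                         tibble::tibble(reaction = "BAD",
                                        metabolite = c("sal", "phnl"),
                                        coef = c(-1, 1)))
  rs <- extract_rules(reaction_db(st), cc$toy$mols, 1, cc$reg)
  expect_equal(nrow(rs$rejected), 1L)
  expect_match(rs$rejected$reason, "unbalanced")
  expect_equal(nrow(rs$map), 2L)
})

test_that("rule sets serialize to JSON and back with their registry slice", {
  cc <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_set(cc$rules2, path)
  reg2 <- prime_registry()
  back <- read_rule_set(path, reg2)
  expect_equal(back$lambda, 2L)
  expect_equal(back$rules[, c("rule_id", "moiety", "change")],
               cc$rules2$rules[, c("rule_id", "moiety", "change")],
               ignore_attr = TRUE)
  expect_setequal(unlist(back$info$member_reactions),
                  unlist(cc$rules2$info$member_reactions))
  # restored registry reproduces the same primes for the same environments
  sal_sig <- mol_signature(cc$toy$mols$sal, 2, reg2)
  expect_equal(sig_string(sal_sig),
               sig_string(mol_signature(cc$toy$mols$sal, 2, cc$reg)))
})

test_that("charge is part of the atom key: carboxylate and acid do not collide", {
  charged <- toy_decarboxylase_db(charged = TRUE)
  reg <- prime_registry()
  s_neutral <- mol_signature(toy_decarboxylase_db()$mols$sal, 1, reg)
  s_anion <- mol_signature(charged$mols$sal, 1, reg)
  expect_false(identical(sig_string(s_neutral), sig_string(s_anion)))
})
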