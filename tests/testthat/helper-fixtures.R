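# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.cache$toy)) {
    toy <- toy_decarboxylase_db()
    reg <- prime_registry()
    .cache$toy <- toy
    .cache$reg <- reg
    .cache$rules1 <- extract_rules(toy$db, toy$mols, 1, reg)
    .cache$rules2 <- extract_rules(toy$db, toy$mols, 2, reg)
    .cache$sigs1 <- signature_index(toy$mols, 1, reg)
    .cache$sigs2 <- signature_index(toy$mols, 2, reg)
  }
  .cache
}

# the solved toy enumeration, shared by design and acceptance tests
toy_pathways <- function() {
  cc <- toy_fixture()
  if (is.null(.cache$ps)) {
    model <- build_design_model(toy_design(), cc$toy$db, cc$rules2, cc$sigs2,
                                cc$toy$thermo)
    .cache$toy_model <- model
    .cache$ps <- solve_pathways(model, k = 10)
  }
  .cache
}

# apply a random atom permutation to a molecule
permute_molecule <- function(mol, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  molecule(mol$atoms[perm, ],
           data.frame(from = inv[mol$bonds$from], to = inv[mol$bonds$to],
                      order = mol$bonds$order),
           id = mol$id)
}

sig_string <- function(sig) paste0(sig$moiety, ":", sig$count, collapse = ";")

label_fingerprint <- function(mol, lambda, reg) {
  paste(sort(atom_labels(mol, lambda, reg)$key), collapse = "|")
}
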