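test_that("SMILES parsing expands hydrogens and perceives simple structures", {
  co2 <- parse_structure("O=C=O", id = "co2")
  expect_equal(nrow(co2$atoms), 3L)
  expect_equal(sort(co2$atoms$element), c("C", "O", "O"))
  expect_equal(co2$bonds$order, c(2, 2))

  phenol <- parse_structure("c1ccccc1O", id = "phenol")
  expect_equal(nrow(phenol$atoms), 13L)  # C6H6O after H expansion
  ec <- element_counts(phenol)
  expect_equal(ec$count[match(c("C", "H", "O"), ec$element)], c(6L, 6L, 1L))
  # aromatic ring bonds kept as a distinct order, never kekulized
  expect_equal(sum(phenol$bonds$order == 1.5), 6L)

  charged <- parse_structure("[O-]C(=O)c1ccccc1O", id = "sal-anion")
  expect_equal(sum(charged$atoms$charge), -1L)
  expect_equal(sum(charged$atoms$element == "H"), 5L)
})

test_that("malformed or unsupported input fails loudly, never silently", {
  expect_error(parse_structure("C(", "smiles"), "unmatched|unclosed|parse")
  expect_error(parse_structure("C1CC", "smiles"), "ring")
  expect_error(parse_structure("[Xx]", "smiles"), "element")
  expect_error(parse_structure("not a molfile", "molfile"), "molfile")
})

test_that("molecular formulas agree with an independent cheminformatics toolkit", {
  smis <- c("OC(=O)c1cccc(C(O)=O)c1O", "OC(=O)c1ccccc1O", "Oc1ccccc1",
            "O=C=O", "NCNCO", "C=O")
  ours <- vapply(smis, function(s) molecular_formula(parse_structure(s)),
                 character(1))
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "for s in sys.argv[1:]:",
    "    print(CalcMolFormula(Chem.AddHs(Chem.MolFromSmiles(s))))",
    sep = "\n")
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(script, f)
  theirs <- system2("python", c(f, shQuote(smis)), stdout = TRUE)
  expect_equal(unname(ours), theirs)
})

test_that("element counts are permutation invariant and additive", {
  cc <- toy_fixture()
  set.seed(42)
  for (mol in cc$toy$mols) {
    perm <- sample(nrow(mol$atoms))
    expect_equal(element_counts(permute_molecule(mol, perm)),
                 element_counts(mol))
  }
  ec <- function(m) tibble::deframe(element_counts(m))
  a <- cc$toy$mols$co2; b <- cc$toy$mols$phnl
  u <- molecule(rbind(a$atoms, b$atoms),
                rbind(a$bonds, transform(b$bonds,
                                         from = from + nrow(a$atoms),
                                         to = to + nrow(a$atoms))),
                id = "union")
  both <- ec(u)
  expect_equal(both[["C"]], ec(a)[["C"]] + ec(b)[["C"]])
  expect_equal(both[["O"]], ec(a)[["O"]] + ec(b)[["O"]])
})

test_that("SMILES and molfile dialects give identical signatures", {
  cc <- toy_fixture()
  mf <- system.file("extdata", "salicylate.mol", package = "moietypath")
  sal_mol <- parse_structure(paste(readLines(mf), collapse = "\n"),
                             dialect = "molfile", id = "sal")
  for (lam in 1:3) {
    expect_equal(sig_string(mol_signature(sal_mol, lam, cc$reg)),
                 sig_string(mol_signature(cc$toy$mols$sal, lam, cc$reg)))
  }
})

test_that("parse -> write -> reparse preserves the molecular graph", {
  cc <- toy_fixture()
  for (mol in cc$toy$mols) {
    smi <- write_smiles(mol, cc$reg)
    back <- parse_structure(smi, id = mol$id)
    expect_equal(label_fingerprint(back, 3, cc$reg),
                 label_fingerprint(mol, 3, cc$reg))
  }
  # disconnected records survive the round trip too
  salt <- parse_structure("O=C=O.Oc1ccccc1", id = "salt")
  back <- parse_structure(write_smiles(salt, cc$reg))
  expect_equal(label_fingerprint(back, 3, cc$reg),
               label_fingerprint(salt, 3, cc$reg))
})

test_that("structure tables round-trip through SMILES and SDF files", {
  cc <- toy_fixture()
  dir <- withr::local_tempdir()
  smi_path <- file.path(dir, "mols.tsv")
  readr::write_tsv(tibble::tibble(id = names(cc$toy$mols),
                                  smiles = vapply(cc$toy$mols, `[[`,
                                                  character(1), "source")),
                   smi_path)
  mols2 <- read_structures(smi_path)
  expect_named(mols2, names(cc$toy$mols))
  sdf_path <- file.path(dir, "mols.sdf")
  write_sdf(cc$toy$mols, sdf_path)
  mols3 <- read_structures(sdf_path)
  for (id in names(cc$toy$mols)) {
    expect_equal(label_fingerprint(mols3[[id]], 3, cc$reg),
                 label_fingerprint(cc$toy$mols[[id]], 3, cc$reg))
  }
})
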