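test_that("structures parse to the expected heavy-atom graphs", {
  w <- parse_structure("O", "smiles")
  expect_equal(n_atoms(w), 1)
  expect_equal(w$atoms$element, "O")
  expect_equal(w$atoms$hydrogens, 2L)

  e <- parse_structure("CCO", "smiles")
  expect_equal(n_atoms(e), 3)
  expect_equal(nrow(e$bonds), 2)
  expect_true(all(e$bonds$order == "1"))

  # charges survive parsing
  ac <- parse_structure("CC(=O)[O-]", "smiles")
  expect_equal(sum(ac$atoms$charge), -1L)

  # molfile input goes through the same normalization
  mol_txt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL", "CCO\n"))
  m2 <- parse_structure(mol_txt, "molfile")
  expect_equal(n_atoms(m2), 3)

  expect_error(parse_structure("", "smiles"), "non-empty")
  expect_error(parse_structure("xx(", "smiles"))
})

test_that("4-coumarate has 12 heavy atoms", {
  cou <- parse_structure("OC(=O)C=Cc1ccc(O)cc1", "smiles")
  expect_equal(n_atoms(cou), 12)   # C9 + O3 of C9H8O3
})

test_that("atomic signatures follow the label and diameter conventions", {
  methane <- parse_structure("C", "smiles")
  expect_equal(atomic_signature(methane, 1, 0)$text, "[C;H4;0]")
  expect_error(atomic_signature(methane, 1, 3), "even")
  expect_error(atomic_signature(methane, 2, 0), "out of range")

  # ethanol rooted at O, d=2: O with one single-bonded carbon neighbor
  eth <- parse_structure("CCO", "smiles")
  o_idx <- which(eth$atoms$element == "O")
  sig <- atomic_signature(eth, o_idx, 2)$text
  expect_match(sig, "^\\[O;H1;0\\]\\(-\\[C;H2;0\\]\\)$")

  # benzene symmetry: all six atoms identical at d=2
  bz <- parse_structure("c1ccccc1", "smiles")
  texts <- vapply(1:6, function(i) atomic_signature(bz, i, 2)$text, "")
  expect_length(unique(texts), 1)
})

test_that("molecular signatures count every heavy atom", {
  expect_equal(unclass(molecular_signature(parse_structure("O", "smiles"), 0)),
               c("[O;H2;0]" = 1L), ignore_attr = TRUE)
  expect_equal(unname(as.integer(
    molecular_signature(parse_structure("CC", "smiles"), 0))), 2L)
  sig <- molecular_signature(parse_structure("CCO", "smiles"), 2)
  expect_length(sig, 3)          # three non-isomorphic neighborhoods
  expect_true(all(sig == 1))
  # sum of counts equals heavy-atom count, also on rings and charges
  for (smi in c("c1ccccc1O", "CC(=O)[O-]", "O=C=O")) {
    m <- parse_structure(smi, "smiles")
    expect_equal(sum(molecular_signature(m, 4)), n_atoms(m))
  }
})

test_that("signatures are invariant under atom relabeling", {
  smis <- c("CCO", "c1ccccc1O", "NC(Cc1ccc(O)cc1)C(=O)O", "CC(=O)[O-]")
  set.seed(7)
  for (smi in smis) {
    m <- parse_structure(smi, "smiles")
    ref <- lapply(c(0, 2, 4), function(d) molecular_signature(m, d))
    for (rep in 1:25) {
      perm <- sample(n_atoms(m))
      m2 <- relabel_molecule(m, perm)
      for (k in seq_along(ref))
        expect_identical(unclass(molecular_signature(m2, c(0, 2, 4)[k])),
                         unclass(ref[[k]]))
    }
  }
})

test_that("equal signatures at a diameter imply equality at smaller diameters", {
  m <- parse_structure("CC(C)Cc1ccc(C)cc1C", "smiles")
  n <- n_atoms(m)
  for (d in c(6, 4, 2)) {
    big <- vapply(seq_len(n), function(i) atomic_signature(m, i, d)$text, "")
    for (dsmall in seq(0, d - 2, by = 2)) {
      small <- vapply(seq_len(n), function(i)
        atomic_signature(m, i, dsmall)$text, "")
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (big[i] == big[j]) expect_identical(small[i], small[j])
      }
    }
  }
})

test_that("tanimoto is a bounded symmetric similarity with identity at 1", {
  v <- molecular_signature(parse_structure("CCO", "smiles"), 2)
  expect_equal(tanimoto(v, v), 1)
  a <- signature_vector(c(x = 2L), 0)
  b <- signature_vector(c(x = 1L, y = 1L), 0)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(b, a), 1 / 3)
  disj <- signature_vector(c(z = 3L), 0)
  expect_equal(tanimoto(a, disj), 0)
  expect_equal(tanimoto(signature_vector(setNames(integer(0), character(0)), 0),
                        signature_vector(setNames(integer(0), character(0)), 0)),
               1)
  expect_error(tanimoto(a, signature_vector(c(x = 1L), 2)), "diameter")
  # property: bounds and identity-iff over random multisets
  set.seed(11)
  for (i in 1:50) {
    ka <- sample(letters[1:6], sample(1:4, 1))
    kb <- sample(letters[1:6], sample(1:4, 1))
    va <- signature_vector(setNames(sample(1:5, length(ka), TRUE), ka), 0)
    vb <- signature_vector(setNames(sample(1:5, length(kb), TRUE), kb), 0)
    tm <- tanimoto(va, vb)
    expect_gte(tm, 0); expect_lte(tm, 1)
    expect_equal(tm, tanimoto(vb, va))
    if (tm == 1) expect_identical(unclass(va)[order(names(va))],
                                  unclass(vb)[order(names(vb))])
  }
})

test_that("signature vectors round-trip through TSV bit-exactly", {
  sig <- molecular_signature(parse_structure("NC(Cc1ccc(O)cc1)C(=O)O",
                                             "smiles"), 4)
  f <- tempfile(fileext = ".tsv")
  write_signature_tsv(sig, f)
  back <- read_signature_tsv(f)
  expect_identical(unclass(back), unclass(sig))
  expect_identical(attr(back, "diameter"), attr(sig, "diameter"))
})
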