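test_that("sign tokens split into subgroup and position IDs", {
  s <- parse_sign_list(c("110", "210"), N = 2)
  expect_equal(s$subgroup, c(1L, 2L))
  expect_equal(s$position, c(10L, 10L))
  ax <- parse_sign_list("011")
  expect_equal(ax$subgroup, 0L)
  expect_equal(ax$position, 11L)
})

test_that("the full printed 21-token sign list parses as 2x10 + 1 axis", {
  toks <- strsplit(paste("11 12 13 14 15 16 17 18 19 110",
                         "21 22 23 24 25 26 27 28 210 29 011"), " ")[[1]]
  s <- parse_sign_list(toks, N = 2)
  expect_equal(sum(s$subgroup == 1), 10L)
  expect_equal(sum(s$subgroup == 2), 10L)
  expect_equal(sum(s$subgroup == 0), 1L)
  expect_setequal(s$position[s$subgroup == 1], 1:10)
  expect_setequal(s$position[s$subgroup == 2], 1:10)
})

test_that("malformed sign lists are rejected with context", {
  expect_error(parse_sign_list(c("11", "31"), N = 2), "subgroup ID")
  expect_error(parse_sign_list(c("11", "1"), N = 1), "malformed")
  expect_error(parse_sign_list(c("11", "11"), N = 1), "duplicate")
  expect_error(parse_sign_list("11", N = 10), "> 9")
})

test_that("orbital blocks parse degeneracies and labels", {
  b <- parse_orbital_block("1|2|1|1", "BU|BG|AU|AG")
  expect_equal(nrow(b), 4L)
  expect_equal(sum(b$degeneracy), 5L)
  expect_equal(b$degeneracy[b$label == "BG"], 2L)
  one <- parse_orbital_block("1", "AG")
  expect_equal(nrow(one), 1L)
  expect_error(parse_orbital_block("1|2", "BU"), "disagree")
  expect_error(parse_orbital_block("1|x", "BU|AG"), "positive integers")
})

test_that("a C2h record with 2x3 atoms plus one axis atom reads 7 on line 1", {
  unit <- asymmetric_unit(
    molecule(c("C", "O", "H"),
             rbind(c(1.5, 0.4, 0), c(2.8, 0.9, 0), c(3.9, 1.1, 0))),
    "C2h", molecule("N", matrix(0, 1, 3)))
  mol <- expand_primitive(unit)$molecule
  rec <- qmsym_record(mol, "C2h")
  lines <- write_record(rec)
  expect_equal(lines[1], "7")
  expect_length(lines, 2 + 7)
  expect_equal(rec$N, 2L)
  expect_equal(rec$n_a, 3L)
  expect_true(rec$has_axis_atoms)
  expect_equal(sum(startsWith(rec$signs, "0")), 1L)
})

test_that("benzene as a CH unit writes 6 subgroups of 2 with count 12", {
  rec <- qmsym_record(benzene(), "D6h")
  lines <- write_record(rec)
  expect_equal(lines[1], "12")
  expect_equal(rec$N, 6L)
  expect_equal(rec$n_a, 2L)
  expect_false(rec$has_axis_atoms)
})

test_that("unpopulated DFT properties are written as the NA sentinel", {
  rec <- qmsym_record(benzene(), "D6h")
  toks <- strsplit(write_record(rec)[2], "\\s+")[[1]]
  expect_equal(toks[1], "D6h")
  expect_true(all(toks[2:22] == "NA"))   # 19 numerics + 2 orbital blocks
  expect_equal(length(toks), 1 + 19 + 2 + 12)
})

test_that("parse is the inverse of write, field for field", {
  set.seed(91)
  for (i in 1:20) {
    rec <- random_record()
    lines <- write_record(rec)
    back <- parse_record(lines)
    expect_equal(back$group, rec$group)
    expect_equal(back$signs, rec$signs)
    expect_equal(back$N, rec$N)
    expect_equal(back$n_a, rec$n_a)
    expect_equal(back$molecule$elements, rec$molecule$elements)
    expect_lt(max(abs(back$molecule$coords - rec$molecule$coords)), 1e-6)
    for (nm in names(rec$properties)) {
      expect_equal(back$properties[[nm]], rec$properties[[nm]],
                   tolerance = 1e-5, info = nm)
    }
    if (is.null(rec$orbitals)) {
      expect_null(back$orbitals)
    } else {
      expect_equal(back$orbitals$occupied$label,
                   rec$orbitals$occupied$label)
      expect_equal(back$orbitals$virtual$degeneracy,
                   rec$orbitals$virtual$degeneracy)
    }
    # a second write is byte-identical: the dialect is a fixed point
    expect_identical(write_record(back), lines)
  }
})

test_that("structural inconsistencies are parse errors", {
  rec <- qmsym_record(benzene(), "D6h")
  lines <- write_record(rec)
  expect_error(parse_record(lines[-3]), "coordinate lines")
  short_signs <- lines
  short_signs[2] <- sub(" 62$", "", short_signs[2])
  expect_error(parse_record(short_signs), "expected")
  bad_el <- lines
  bad_el[3] <- sub("^C ", "O ", bad_el[3])
  expect_error(parse_record(bad_el), "different elements")
})

test_that("validation flags sign swaps and geometric damage", {
  set.seed(17)
  rec <- random_record("C3h")
  v0 <- validate_record(rec)
  expect_true(attr(v0, "passed"))

  # swap two sign tokens across subgroups at different positions
  swapped <- rec
  s <- parse_sign_list(swapped$signs)
  cand <- which(s$subgroup > 0)
  i <- cand[1]
  j <- cand[which(s$position[cand] != s$position[i] &
                    s$subgroup[cand] != s$subgroup[i])][1]
  swapped$signs[c(i, j)] <- swapped$signs[c(j, i)]
  v1 <- validate_record(swapped)
  expect_false(v1$passed[v1$check == "sign_consistency"])

  broken <- rec
  broken$molecule$coords[1, ] <- broken$molecule$coords[1, ] + c(0.5, 0, 0)
  v2 <- validate_record(broken, tol = 0.1)
  expect_false(v2$passed[v2$check == "geometry"])
  expect_false(attr(v2, "passed"))
})

test_that("directory and tar batch readers recover record sets", {
  dir <- withr::local_tempdir()
  set.seed(23)
  recs <- lapply(1:3, function(i) random_record())
  for (i in 1:3) {
    write_record(recs[[i]], file.path(dir, sprintf("QM_sym_%d.xyz", i)))
  }
  got <- read_qmsym_dir(dir)
  expect_length(got, 3L)
  expect_equal(vapply(got, `[[`, "", "group"),
               vapply(recs, `[[`, "", "group"),
               ignore_attr = TRUE)
  tbl <- properties_table(got)
  expect_equal(nrow(tbl), 3L)
  expect_true(all(c("Eg", "Cv", "n_atoms") %in% names(tbl)))

  tarfile <- file.path(withr::local_tempdir(), "QM_sym_xyz_number.tar")
  withr::with_dir(dir, utils::tar(tarfile, files = list.files(dir)))
  from_tar <- read_qmsym_tar(tarfile)
  expect_length(from_tar, 3L)
})
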