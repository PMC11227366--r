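write_mini_obo <- function(path) {
  writeLines(c(
    "format-version: 1.4",
    "data-version: releases/2099-01-01",
    "",
    "[Term]",
    "id: HP:0000256",
    "name: Macrocephaly",
    'synonym: "Increased size of cranium" EXACT []',
    'synonym: "Big cranium" RELATED []',
    "alt_id: HP:0001355",
    "",
    "[Term]",
    "id: HP:0009778",
    "name: Short phalanx",
    "",
    "[Term]",
    "id: HP:0100790",
    "name: Hernia",
    "",
    "[Term]",
    "id: HP:0000001",
    "name: Old term",
    "is_obsolete: true",
    "replaced_by: HP:0100790"
  ), path)
  path
}

write_mini_obographs <- function(path) {
  iri <- function(id) paste0("http://purl.obolibrary.org/obo/", sub(":", "_", id))
  doc <- list(graphs = list(list(
    meta = list(version = "releases/2099-01-01"),
    nodes = list(
      list(id = iri("HP:0000256"), lbl = "Macrocephaly", type = "CLASS",
           meta = list(
             synonyms = list(
               list(pred = "hasExactSynonym", val = "Increased size of cranium"),
               list(pred = "hasRelatedSynonym", val = "Big cranium")
             ),
             basicPropertyValues = list(list(
               pred = "http://www.geneontology.org/formats/oboInOwl#hasAlternativeId",
               val = "HP:0001355"
             ))
           )),
      list(id = iri("HP:0009778"), lbl = "Short phalanx", type = "CLASS"),
      list(id = iri("HP:0100790"), lbl = "Hernia", type = "CLASS"),
      list(id = iri("HP:0000001"), lbl = "Old term", type = "CLASS",
           meta = list(
             deprecated = TRUE,
             basicPropertyValues = list(list(
               pred = "http://purl.obolibrary.org/obo/IAO_0100001",
               val = iri("HP:0100790")
             ))
           ))
    )
  )))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  path
}

test_that("parse_ontology reads OBO concepts, synonyms, alt_ids, obsolescence", {
  f <- write_mini_obo(withr::local_tempfile(fileext = ".obo"))
  concepts <- parse_ontology(f)
  expect_length(concepts, 4L)
  expect_equal(attr(concepts, "version"), "releases/2099-01-01")
  mac <- concepts[[1L]]
  expect_equal(mac$id, "HP:0000256")
  expect_equal(mac$label, "Macrocephaly")
  expect_equal(mac$synonyms, c("Increased size of cranium", "Big cranium"))
  expect_equal(mac$synonym_scopes, c("EXACT", "RELATED"))
  expect_equal(mac$alt_ids, "HP:0001355")
  old <- concepts[[4L]]
  expect_true(old$obsolete)
  expect_equal(old$replaced_by, "HP:0100790")
})

test_that("obographs JSON yields the same concept list as the OBO rendering", {
  obo <- parse_ontology(write_mini_obo(withr::local_tempfile(fileext = ".obo")))
  og <- parse_ontology(write_mini_obographs(withr::local_tempfile(fileext = ".json")))
  expect_equal(unclass(og), unclass(obo), ignore_attr = TRUE)
  expect_equal(attr(og, "version"), attr(obo, "version"))
})

test_that("parse_ontology flags malformed input and id collisions", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: x", "alt_id: A:2",
               "", "[Term]", "id: A:2", "name: y"), f)
  expect_error(parse_ontology(f), "alt_id collides")

  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f2)
  expect_error(parse_ontology(f2, format = "obographs-json"), "cannot parse")
})

test_that("tokenize_surface splits on non-alphanumerics, lowercased, in order", {
  expect_equal(tokenize_surface("Increased size of cranium"),
               c("increased", "size", "of", "cranium"))
  expect_equal(tokenize_surface(""), character(0))
  expect_equal(tokenize_surface("cleft lip/palate"), c("cleft", "lip", "palate"))
  expect_equal(tokenize_surface("Short-stature, severe!"),
               c("short", "stature", "severe"))
  expect_equal(tokenize_surface("type 1"), c("type", "1"))
})

test_that("filter_blacklist removes stop words, verbs and conjunctions in order", {
  expect_equal(filter_blacklist(c("increased", "size", "of", "cranium")),
               c("increased", "size", "cranium"))
  expect_equal(filter_blacklist(c("of", "the")), character(0))
  expect_equal(filter_blacklist(c("short", "and", "broad", "toes")),
               c("short", "broad", "toes"))
})

test_that("consolidate maps tokens to cluster IDs and reports misses", {
  v <- build_clusters(c("increased", "size", "cranium"))
  ok <- consolidate(c("increased", "size", "cranium"), v)
  expect_length(ok$cluster_ids, 3L)
  expect_length(ok$missing, 0L)
  expect_equal(consolidate(character(0), v),
               list(cluster_ids = character(0), missing = character(0)))
  miss <- consolidate(c("increased", "zzz"), v)
  expect_equal(miss$missing, "zzz")
  # digit-bearing tokens get implicit singleton clusters keyed by themselves
  num <- consolidate(c("increased", "1"), v)
  expect_equal(num$cluster_ids[[2L]], "1")
  expect_length(num$missing, 0L)
})

test_that("make_signature sorts unique IDs and keeps the duplicated length", {
  s <- make_signature(c("C3425", "C112", "C59"))
  expect_equal(s$key, "C112-C3425-C59")
  expect_equal(s$length, 3L)
  s2 <- make_signature(c("C2", "C26", "C35"))
  expect_equal(s2$key, "C2-C26-C35")
  expect_equal(s2$length, 3L)
  s3 <- make_signature(c("C7", "C7"))
  expect_equal(s3$key, "C7")
  expect_equal(s3$length, 2L)
  expect_error(make_signature(character(0)), "empty surface")
})

test_that("signatures are invariant under token permutation", {
  set.seed(5)
  for (rep in 1:25) {
    ids <- paste0("C", sample(1:500, sample(1:6, 1L), replace = TRUE))
    s1 <- make_signature(ids)
    s2 <- make_signature(sample(ids))
    expect_identical(s1, s2)
  }
})

test_that("build_index reproduces the worked indexing example via line-numbered clusters", {
  cf <- write_worked_example_clusters(withr::local_tempfile(fileext = ".txt"))
  v <- load_clusters(cf)
  expect_equal(cluster_of(v, "increased"), "C2")
  expect_equal(cluster_of(v, "size"), "C26")
  expect_equal(cluster_of(v, "cranium"), "C35")
  concepts <- make_concepts(
    make_concept("HP:0000256", "Macrocephaly",
                 synonyms = "Increased size of cranium")
  )
  idx <- build_index(concepts, v)
  keys <- vapply(idx$signatures, `[[`, character(1), "key")
  lens <- vapply(idx$signatures, `[[`, integer(1), "length")
  hit <- which(keys == "C2-C26-C35" & lens == 3L)
  expect_length(hit, 1L)
  m <- idx$signatures[[hit]]$matches
  expect_length(m, 1L)
  expect_equal(m[[1L]]$id, "HP:0000256")
  expect_equal(m[[1L]]$surface, "Increased size of cranium")
  expect_false(m[[1L]]$is_label)
})

test_that("build_index closes over cluster variants and stores nothing else", {
  idx <- mini_index()
  tm <- idx$token_map
  # every member of a used cluster is present with the same ID
  v <- mini_vocab()
  for (cid in unique(unname(tm[!grepl("[0-9]", names(tm))]))) {
    members <- normalize_spelling(v$clusters[[cid]])
    expect_true(all(members %in% names(tm)))
    expect_true(all(tm[members] == cid))
  }
  # tokens from clusters that touch no surface are absent: "shore" is not
  # in the vocabulary at all, and no unused-cluster token leaks in
  used <- unique(unname(tm))
  all_used_members <- unlist(lapply(used[grepl("^C", used)],
                                    function(cid) normalize_spelling(v$clusters[[cid]])))
  expect_setequal(names(tm)[!grepl("[0-9]", names(tm))], unique(all_used_members))
})

test_that("empty, skipped and ambiguous surfaces are handled at index time", {
  v <- build_clusters(c("hernia", "umbilical"))
  concepts <- make_concepts(
    make_concept("X:1", "Of the"),              # empty after filtering
    make_concept("X:2", "Unknown zebra thing"), # uncovered tokens
    make_concept("X:3", "Umbilical hernia"),
    make_concept("X:4", "Hernia umbilical")     # same cluster set + length
  )
  expect_equal(nrow(build_index(make_concepts(), v)$skipped), 0L)
  idx <- build_index(concepts, v)
  expect_equal(idx$metadata$n_indexed_surfaces, 2L)
  expect_equal(nrow(idx$skipped), 2L)
  expect_match(idx$skipped$reason[[1L]], "empty after filtering")
  expect_match(idx$skipped$reason[[2L]], "no cluster for")
  # ambiguity retained as a two-entry list under one signature
  lens <- vapply(idx$signatures, `[[`, integer(1), "length")
  two <- idx$signatures[[which(lens == 2L)]]
  expect_length(two$matches, 2L)
  expect_setequal(vapply(two$matches, `[[`, character(1), "id"), c("X:3", "X:4"))
})

test_that("obsolete concepts are excluded from the index", {
  concepts <- make_concepts(
    make_concept("X:1", "Hernia"),
    make_concept("X:9", "Hernia old", obsolete = TRUE, replaced_by = "X:1")
  )
  idx <- build_index(concepts, build_clusters(c("hernia", "old")))
  ids <- unlist(lapply(idx$signatures, function(s) {
    vapply(s$matches, `[[`, character(1), "id")
  }))
  expect_equal(unique(ids), "X:1")
})

test_that("exact_synonyms_only restricts indexed synonym scopes", {
  concepts <- make_concepts(
    make_concept("X:1", "Hernia", synonyms = c("Umbilical hernia"),
                 scopes = "BROAD")
  )
  v <- build_clusters(c("hernia", "umbilical"))
  expect_equal(build_index(concepts, v)$metadata$n_indexed_surfaces, 2L)
  expect_equal(build_index(concepts, v, exact_synonyms_only = TRUE)$
                 metadata$n_indexed_surfaces, 1L)
})

test_that("index serialization round-trips field-for-field and is byte-stable", {
  idx <- mini_index()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_index(idx, f1)
  loaded <- load_index(f1)
  expect_equal(loaded$schema_version, idx$schema_version)
  expect_equal(loaded$blacklist, unname(idx$blacklist))
  expect_equal(loaded$token_map, idx$token_map)
  expect_equal(loaded$signatures, idx$signatures)
  expect_equal(loaded$metadata$ontology_version, idx$metadata$ontology_version)
  # rebuild from identical inputs -> byte-identical file
  save_index(build_index(mini_concepts(), mini_vocab()), f2)
  expect_identical(readLines(f1), readLines(f2))
  # saved and re-saved loaded index agree too
  f3 <- withr::local_tempfile(fileext = ".json")
  save_index(loaded, f3)
  expect_identical(readLines(f1), readLines(f3))
})

test_that("load_index rejects schema mismatches and truncated files", {
  idx <- mini_index()
  f <- withr::local_tempfile(fileext = ".json")
  save_index(idx, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$schema_version <- "99"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), f)
  expect_error(load_index(f), "schema version mismatch")

  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 40), f2)
  expect_error(load_index(f2), "cannot parse")
})
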