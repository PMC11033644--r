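classify_text <- function(txt, rules = default_ruleset()) {
  hits <- detect_mentions(note_tbl(txt))
  classify_mentions(hits, rules)
}

test_that("worked examples label as expected: relevant mentions", {
  relevant <- c("complains of pain",
                "experiencing headaches",
                "worsening back pain",
                "has stomach cramps",
                "has muscle aches")
  for (txt in relevant) {
    cl <- classify_text(txt)
    expect_equal(nrow(cl), 1, label = txt)
    expect_equal(cl$label, "relevant", label = txt)
    expect_equal(cl$category, "affirmed", label = txt)
  }
})

test_that("worked examples label as expected: not-relevant categories", {
  cases <- list(
    list("denied pain this morning", "negated"),
    list("no complaint of pain", "negated"),
    list("experiencing other physical symptoms? for example, chest pain",
         "form"),
    list("pained and decorated the walls", "misspelling"),
    list("fear that eating will cause throat pain", "hypothetical"),
    list("reduce risk of pressure sores", "hypothetical"),
    list("life is too painful to carry on living", "metaphorical"),
    list("pain will end when she repents", "metaphorical"),
    list("defensive of painful feelings", "metaphorical"),
    list("painful consequences of using alcohol", "metaphorical")
  )
  for (case in cases) {
    cl <- classify_text(case[[1]])
    expect_true(nrow(cl) >= 1, label = case[[1]])
    expect_true(all(cl$label == "not_relevant"), label = case[[1]])
    expect_true(all(cl$category == case[[2]]),
                label = paste(case[[1]], "->", case[[2]]))
  }
})

test_that("negation scope is windowed and reset by 'but'", {
  cl <- classify_text("was in pain but now denies any discomfort")
  expect_equal(cl$category[cl$term == "pain"], "affirmed")
  expect_equal(cl$category[cl$term == "discomfort"], "negated")
  # a conjunction between the cue and the hit resets the negation scope
  far <- classify_text(
    "denies low mood but states that the recently worsening knee pain persists")
  expect_equal(far$category[far$term == "pain"], "affirmed")
  # sentence-initial cue governs across the window
  init <- classify_text("no report from physio of any new onset of pain")
  expect_equal(init$category, "negated")
})

test_that("classification is exhaustive with exactly one label per hit", {
  co <- small_cohort()
  hits <- detect_mentions(co$notes[1:100, ])
  cl <- classify_mentions(hits)
  expect_equal(nrow(cl), nrow(hits))
  expect_true(all(cl$label %in% c("relevant", "not_relevant")))
  expect_true(all(cl$category[cl$label == "relevant"] == "affirmed"))
  expect_true(all(cl$category[cl$label == "not_relevant"] %in%
                    c("negated", "form", "misspelling", "hypothetical",
                      "metaphorical")))
  expect_true(all(!is.na(cl$trigger)))
  counts <- mention_counts(cl)
  expect_equal(sum(counts$n), nrow(cl))
  # empty stream in, empty stream out
  expect_equal(nrow(classify_mentions(hits[0, ])), 0)
})

test_that("patient rollup implements the class definitions", {
  pats <- tibble::tibble(patient_id = c("a", "b", "c"))
  notes <- tibble::tibble(
    note_id = c("n1", "n2"),
    patient_id = c("a", "b"),
    text = c("Denied pain this morning. No complaint of pain.",
             "Reports worsening back pain."))
  cl <- classify_mentions(detect_mentions(notes))
  rolled <- rollup_patients(cl, pats)
  expect_equal(rolled$pain_class[rolled$patient_id == "a"], "class0")
  expect_equal(rolled$pain_class[rolled$patient_id == "b"], "class1")
  expect_equal(rolled$pain_class[rolled$patient_id == "c"], "class0")
  expect_equal(rolled$n_mentions[rolled$patient_id == "c"], 0L)
  expect_equal(sum(rolled$pain_class %in% c("class0", "class1")), nrow(pats))
  # adding a relevant mention never demotes a patient
  notes2 <- dplyr::bind_rows(
    notes, tibble::tibble(note_id = "n3", patient_id = "a",
                          text = "Complains of headache."))
  rolled2 <- rollup_patients(classify_mentions(detect_mentions(notes2)), pats)
  expect_equal(rolled2$pain_class[rolled2$patient_id == "a"], "class1")
  expect_equal(rolled2$pain_class[rolled2$patient_id == "b"], "class1")
})

test_that("mentions outside the cohort are dropped with a warning", {
  notes <- tibble::tibble(note_id = "n1", patient_id = "ghost",
                          text = "Complains of pain.")
  cl <- classify_mentions(detect_mentions(notes))
  expect_warning(
    rolled <- rollup_patients(cl, tibble::tibble(patient_id = "a")),
    "outside the cohort")
  expect_equal(rolled$pain_class, "class0")
})

test_that("a custom rule set file changes classification behaviour", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    negation = list(scope = 1, cues = list("denied")),
    hypothetical = list(scope = 2, cues = list("risk of")),
    form_patterns = list("zzz-never"),
    misspelling_patterns = list("zzz-never"),
    metaphorical_patterns = list("zzz-never")
  ), path)
  rules <- load_ruleset(path)
  # "no" is not a cue in this rule set
  cl <- classify_text("no complaint of pain", rules)
  expect_equal(cl$category, "affirmed")
  expect_equal(classify_text("denied pain", rules)$category, "negated")
})
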