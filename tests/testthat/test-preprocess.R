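test_that("missing-value tokens collapse to NA and terms are trimmed", {
  expect_true(is.na(normalize_missing("UNKNOWN")))
  expect_true(is.na(normalize_missing("unk")))
  expect_true(is.na(normalize_missing("()")))
  expect_true(is.na(normalize_missing("   ")))
  expect_identical(normalize_missing(" Tramadol "), "Tramadol")
  # vectorised over a mixed column
  expect_identical(normalize_missing(c("UNK", "pain", "")),
                   c(NA, "pain", NA))
})

test_that("dose dichotomy uses a strict threshold with 100 mg in the low class", {
  expect_identical(categorize_dose(650), "larger than 100 mg")
  expect_identical(categorize_dose(50), "less than 100 mg")
  expect_identical(categorize_dose(100), "less than 100 mg")
  expect_identical(categorize_dose(100.01), "larger than 100 mg")
  expect_error(categorize_dose(-1), "negative")
})

test_that("dose unit conversion maps unknown units to missing", {
  expect_equal(convert_dose_mg(c(0.65, 650, 650000), c("g", "mg", "ug")),
               c(650, 650, 650))
  expect_true(is.na(convert_dose_mg(1, "iu")))
  expect_true(is.na(categorize_dose(convert_dose_mg(1, "iu"))))
})

test_that("age binning covers the four groups with 65 in the oldest", {
  expect_identical(categorize_age(c(0, 17, 18, 39, 40, 64, 65, 90)),
                   c("<18", "<18", "18-39", "18-39", "40-64", "40-64",
                     "65+", "65+"))
  expect_error(categorize_age(-3), "negative")
})

test_that("endpoint labeling partitions reports into three exhaustive classes", {
  sch <- tiny_schema()
  expect_identical(label_endpoint(tiny_reports(), sch),
                   c("positive", "negative", "positive"))
  missing_outcome <- case_report("r4", list(gender = "male", drug = "APAP",
                                            `adverse events` = "rash",
                                            outcomes = character(0)))
  expect_identical(label_endpoint(missing_outcome, sch), "excluded")
  # property: fuzzed reports always get exactly one of the three labels
  sim <- default_sim_config(300, seed = 11, missing_rate = 0.3)
  sim$missing_rates[["outcomes"]] <- 0.2
  status <- label_endpoint(generate_cases(sim), sim$schema)
  expect_true(all(status %in% c("positive", "negative", "excluded")))
  expect_true(all(table(status) > 0))
})

test_that("sentence rendering is deterministic, joins multi-values, and masks missing", {
  sch <- default_sim_config(10)$schema
  rep1 <- case_report("x", list(
    gender = "female", age = "18-39", `primary suspect drug` = "APAP",
    dose = "larger than 100 mg", indication = "pain",
    `adverse events` = c("nausea", "vomiting"), outcomes = "death"))
  s1 <- generate_sentence(rep1, sch)
  expect_identical(s1, generate_sentence(rep1, sch))
  expect_match(s1, "nausea and vomiting")
  # endpoint lives in outcomes: whole outcomes clause removed
  expect_false(grepl("death", s1))
  expect_false(grepl("leading to", s1))
  rep2 <- case_report("y", list(gender = character(0), age = character(0),
                                `primary suspect drug` = "tramadol",
                                dose = character(0), indication = character(0),
                                `adverse events` = character(0),
                                outcomes = "recovered"))
  expect_match(generate_sentence(rep2, sch), "unknown")
})

test_that("the rendered sentence never leaks the endpoint term", {
  # adverse-event endpoint: only the endpoint term is excised
  sch_ae <- feature_schema(
    features = c("gender", "age", "primary suspect drug", "dose",
                 "indication", "adverse events", "outcomes"),
    vocab = list(gender = c("female", "male"),
                 age = c("<18", "65+"),
                 `primary suspect drug` = c("APAP", "tramadol"),
                 dose = c("less than 100 mg", "larger than 100 mg"),
                 indication = c("pain", "fever"),
                 `adverse events` = c("hepatitis", "nausea", "rash"),
                 outcomes = c("death", "recovered")),
    endpoint_feature = "adverse events", endpoint_term = "hepatitis",
    multi_valued = c("adverse events", "outcomes"))
  pvprobe:::with_seed(21, {
    for (i in 1:50) {
      vals <- list(gender = sample(c("female", "male", ""), 1),
                   age = sample(sch_ae$vocab$age, 1),
                   `primary suspect drug` = sample(sch_ae$vocab$`primary suspect drug`, 1),
                   dose = sample(sch_ae$vocab$dose, 1),
                   indication = sample(sch_ae$vocab$indication, 1),
                   `adverse events` = sample(sch_ae$vocab$`adverse events`,
                                             sample(0:3, 1)),
                   outcomes = sample(sch_ae$vocab$outcomes, sample(1:2, 1)))
      vals <- lapply(vals, function(v) v[nzchar(v)])
      r <- case_report(paste0("f", i), vals)
      s <- generate_sentence(r, sch_ae)
      expect_false(grepl("hepatitis", s, fixed = TRUE))
      if ("nausea" %in% vals$`adverse events`)
        expect_match(s, "nausea")
    }
  })
  # outcomes endpoint: no outcomes term at all appears
  sim <- default_sim_config(80, seed = 31)
  sent <- generate_sentences(generate_cases(sim), sim$schema)
  for (tm in sim$schema$vocab$outcomes)
    expect_false(any(grepl(tm, sent$text, fixed = TRUE)))
})

test_that("stratified split conserves classes, hits exact multiples, is seeded", {
  recs <- data.frame(report_id = sprintf("r%03d", 1:200),
                     text = "x", label = rep(c(1, 0), each = 100),
                     stringsAsFactors = FALSE)
  sp <- stratified_split(recs, seed = 5)
  for (s in names(sp)) {
    expect_equal(sum(sp[[s]]$label == 1),
                 c(train = 64, dev = 16, test = 20)[[s]])
    expect_equal(sum(sp[[s]]$label == 0),
                 c(train = 64, dev = 16, test = 20)[[s]])
  }
  # conservation + disjointness on awkward sizes
  recs2 <- data.frame(report_id = sprintf("q%03d", 1:137), text = "x",
                      label = rep(c(1, 0), length.out = 137),
                      stringsAsFactors = FALSE)
  sp2 <- stratified_split(recs2, seed = 9)
  all_ids <- c(sp2$train$report_id, sp2$dev$report_id, sp2$test$report_id)
  expect_length(all_ids, 137)
  expect_false(anyDuplicated(all_ids) > 0)
  # same seed reproduces; different seed differs
  sp2b <- stratified_split(recs2, seed = 9)
  expect_identical(sp2, sp2b)
  sp2c <- stratified_split(recs2, seed = 10)
  expect_false(identical(sp2$train$report_id, sp2c$train$report_id))
  expect_error(stratified_split(recs, ratios = c(train = 0, dev = 0.5,
                                                 test = 0.5)), "zero")
})

test_that("dataset summaries reproduce positive/negative ratios", {
  mk <- function(np, nn) data.frame(report_id = as.character(seq_len(np + nn)),
                                    text = "a b c",
                                    label = rep(c(1, 0), c(np, nn)),
                                    stringsAsFactors = FALSE)
  expect_equal(dataset_summary(mk(15224, 21437))$pos_neg_ratio, 0.71)
  expect_equal(dataset_summary(mk(9846, 17399))$pos_neg_ratio, 0.57)
  expect_equal(dataset_summary(mk(1, 1))$pos_neg_ratio, 1.00)
  s <- dataset_summary(mk(2, 2))
  expect_equal(s$seq_len_mean, 3)
  expect_equal(s$seq_len_sd, 0)
  expect_true(is.na(dataset_summary(mk(3, 0))$pos_neg_ratio))
})

test_that("tf-idf matches direct formula evaluation on a toy corpus", {
  docs <- c("apap liver", "apap nausea", "apap liver")
  # independent direct evaluation: idf = log((1+N)/(1+df)) + 1, tf counts,
  # L2 per document, averaged over the documents containing the term
  N <- 3
  vocab <- c("apap", "liver", "nausea")
  tf <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 0))
  idf <- log((1 + N) / (1 + c(3, 2, 1))) + 1
  w <- sweep(tf, 2, idf, `*`)
  w <- w / sqrt(rowSums(w^2))
  expected <- colSums(w) / colSums(tf > 0)
  got <- tfidf_top_terms(docs, k = 10)
  expect_identical(got$term, vocab[order(-expected, vocab)])
  expect_equal(got$tfidf, unname(sort(expected, decreasing = TRUE)),
               tolerance = 1e-12)
  # rarer term outranks ubiquitous term at equal tf
  expect_true(which(got$term == "nausea") < which(got$term == "apap"))
  # identical one-word documents: the word carries minimum idf, score defined
  one <- tfidf_top_terms(rep("apap", 5), k = 3)
  expect_equal(nrow(one), 1)
  expect_gt(one$tfidf, 0)
  expect_error(tfidf_top_terms(docs, k = 0), "positive")
})
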