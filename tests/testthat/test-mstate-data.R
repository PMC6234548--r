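test_that("structure constructors enforce the transition graph rules", {
  st <- illness_death_structure()
  expect_equal(st$n_states, 3L)
  expect_equal(st$absorbing, 3L)
  expect_true(all(st$clock == "forward"))
  expect_error(transition_structure(3, rbind(c(1, 4))), "lie in")
  expect_error(transition_structure(3, rbind(c(1, 1))), "self")
  expect_error(illness_death_structure(clock = c("1->2" = "reset")),
               "initial state")
  st2 <- progressive_structure(4, clock = c("2->3" = "reset"))
  expect_equal(unname(st2$clock[c("1->2", "2->3", "3->4")]),
               c("forward", "reset", "forward"))
  expect_error(transition_structure(3, rbind(c(1, 2)),
                                    clock = c("1->3" = "forward")),
               "unknown transition")
})

test_that("a subject chain parses from CSV and invalid rows are rejected by name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,from,to,entry,exit,status,z",
               "1,1,2,0,2,1,0.4",
               "1,2,3,2,5,1,0.4"), f)
  ds <- read_long_csv(f, illness_death_structure())
  expect_equal(nrow(ds$records), 2L)
  expect_equal(ds$tau, 5)
  expect_equal(length(unique(ds$records$id)), 1L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,from,to,entry,exit,status,z",
               "1,3,1,0,2,1,0.4"), f2)
  expect_error(read_long_csv(f2, illness_death_structure()),
               "row 1.*absorbing")
})

test_that("chain violations are rejected with row-level diagnostics", {
  st <- illness_death_structure()
  base <- data.frame(id = 1, from = 1, to = 2, entry = 0, exit = 2, status = 1)
  # broken chain: second record does not start where the first ended
  bad <- rbind(base, data.frame(id = 1, from = 2, to = 3, entry = 3,
                                exit = 5, status = 1))
  expect_error(multistate_dataset(bad, st), "does not chain")
  # zero-length sojourn
  expect_error(multistate_dataset(
    data.frame(id = 1, from = 1, to = 2, entry = 0, exit = 0, status = 1), st),
    "exit time must exceed")
  # chain ending with an event into a non-absorbing state
  expect_error(multistate_dataset(base, st), "non-absorbing")
  # transition not in the structure
  expect_error(multistate_dataset(
    data.frame(id = 1, from = 2, to = 1, entry = 0, exit = 2, status = 1), st),
    "not allowed")
})

test_that("round trip write/read is the identity on a simulated cohort", {
  sc <- hivlike_scenario(50)
  sim <- simulate_cohort(sc, seed = 123)
  f <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(sim$dataset, f)
  back <- read_long_csv(f, sim$dataset$structure)
  expect_equal(back$records$id, sim$dataset$records$id)
  expect_equal(back$records$from, sim$dataset$records$from)
  expect_equal(back$records$to, sim$dataset$records$to)
  expect_equal(back$records$status, sim$dataset$records$status)
  expect_equal(back$records$exit, sim$dataset$records$exit, tolerance = 1e-12)
  expect_equal(back$tau, sim$dataset$tau, tolerance = 1e-12)
  expect_equal(back$covariates, sim$dataset$covariates)
  expect_equal(as.character(back$records$marital),
               as.character(sim$dataset$records$marital))
})

test_that("state_at interpolates the chain and marks unobservable times", {
  ds <- toy_illness_death()
  expect_equal(state_at(ds, 1, 3), 2L)   # between 1->2 at 2 and 2->3 at 5
  expect_equal(state_at(ds, 1, 0), 1L)   # initial state
  expect_equal(state_at(ds, 1, 10), 3L)  # absorbed stays absorbed
  expect_equal(state_at(ds, 4, 6), NA_integer_)  # censored at 4 in state 1
  expect_equal(state_at(ds, 2, 7.5), NA_integer_)  # censored at 7 in state 2
  expect_equal(state_at(ds, 1, c(0, 3, 10)), c(1L, 2L, 3L))
  expect_error(state_at(ds, 99, 1), "unknown subject")
})

test_that("transition datasets implement the separate approach", {
  ds <- toy_illness_death()
  td12 <- extract_transition_dataset(ds, c(1, 2))
  expect_equal(nrow(td12$data), 4L)
  expect_equal(sum(td12$data$status), 2L)
  expect_equal(sum(td12$data$status == 0), 2L)
  expect_setequal(td12$data$cens_type[td12$data$status == 0],
                  c("competing", "lost"))
  td23 <- extract_transition_dataset(ds, c(2, 3))
  expect_equal(nrow(td23$data), 2L)  # only visitors of state 2
  expect_error(extract_transition_dataset(ds, c(3, 1)), "not in the structure")
})

test_that("clock reset measures sojourn durations and records entry offsets", {
  st <- illness_death_structure(clock = c("2->3" = "reset"))
  rec <- rbind(
    data.frame(id = 1, from = 1, to = 2, entry = 0, exit = 3, status = 1),
    data.frame(id = 1, from = 2, to = 3, entry = 3, exit = 7, status = 1),
    data.frame(id = 2, from = 1, to = 0, entry = 0, exit = 5, status = 0))
  ds <- multistate_dataset(rec, st)
  td <- extract_transition_dataset(ds, c(2, 3))
  expect_equal(td$data$time, 4)          # 7 - 3 on the sojourn clock
  expect_equal(td$data$entry_offset, 3)
  expect_equal(td$data$entry, 0)         # no delayed entry on a reset clock
  tda <- extract_transition_dataset(ds, c(2, 3), augment_sojourn = TRUE)
  expect_equal(tda$data$d, 3)
  expect_true("d" %in% names(tda$covariates))
  # augmentation is a no-op for the initial state
  td12 <- extract_transition_dataset(ds, c(1, 2), augment_sojourn = TRUE)
  expect_false("d" %in% names(td12$covariates))
})

test_that("event bookkeeping is conserved across transition datasets", {
  sim <- simulate_cohort(hivlike_scenario(200), seed = 11)
  ds <- sim$dataset
  # chain conservation: events per subject = states visited - 1
  per_subj <- tapply(ds$records$status, ds$records$id, sum)
  visited <- tapply(ds$records$from, ds$records$id, length)
  last_event <- tapply(ds$records$status, ds$records$id,
                       function(s) s[length(s)])
  expect_equal(as.numeric(per_subj),
               as.numeric(visited) - 1 + as.numeric(last_event))
  # rows non-increasing along a progressive chain
  n12 <- nrow(extract_transition_dataset(ds, c(1, 2))$data)
  n23 <- nrow(extract_transition_dataset(ds, c(2, 3))$data)
  expect_true(n23 <= n12)
  # events out of h across destinations match raw exits from h
  raw_exits_1 <- sum(ds$records$from == 1 & ds$records$status == 1)
  ev_sum <- sum(extract_transition_dataset(ds, c(1, 2))$data$status)
  expect_equal(ev_sum, raw_exits_1)
})
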