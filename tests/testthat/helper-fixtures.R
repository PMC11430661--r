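# shared test fixtures, built in code

ref_table <- load_reference_table()

# independent closed-form oracle for the four-parameter logistic, kept
# separate from logistic_eval()
oracle_4pl <- function(a1, a2, a3, a4, x) a1 + (a2 - a1) / (1 + exp(-a3 * (x - a4)))

ref_params <- function(tau) {
  row <- which(ref_table$tau == tau)
  unlist(ref_table[row, c("a1", "a2", "a3", "a4")])
}

# small noiseless cohort lying exactly on a known logistic curve
exact_curve_cohort <- function(params, n = 60, ages = seq(2, 70, length.out = n)) {
  data.frame(child_id = sprintf("c%03d", seq_along(ages)),
             age_months = ages,
             score = oracle_4pl(params[1], params[2], params[3], params[4], ages),
             stringsAsFactors = FALSE)
}

# random response set over the 64 items under a local seed
random_responses <- function(seed, p_mostly = 0.5, p_unanswered = 0.1) {
  withr::with_seed(seed, {
    state <- sample(c("mostly", "rarely", "none"), 64, replace = TRUE,
                    prob = c(p_mostly * (1 - p_unanswered),
                             (1 - p_mostly) * (1 - p_unanswered),
                             p_unanswered))
    flip_responses(mostly = which(state == "mostly"),
                   rarely = which(state == "rarely"))
  })
}
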