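# Hand-constructed microdata rows for unit tests. Every argument overrides
# the neutral default; vectors are recycled to n.
make_women <- function(n = 1,
                       weight = 1, age = 30, currently_married = TRUE,
                       method = "none", birth_months = "",
                       bf_months = 0L, amen_months = 0L, abst_months = 0L,
                       hysterectomy = FALSE, hyst_months_ago = NA_integer_,
                       unmet_need = FALSE,
                       state = "S1", region = "R1", residence = "rural",
                       education = "5-9", wealth = "middle",
                       caste = "OBC") {
  data.frame(weight = rep_len(weight, n), age = rep_len(as.integer(age), n),
             currently_married = rep_len(currently_married, n),
             method = rep_len(method, n),
             birth_months = rep_len(birth_months, n),
             bf_months = rep_len(as.integer(bf_months), n),
             amen_months = rep_len(as.integer(amen_months), n),
             abst_months = rep_len(as.integer(abst_months), n),
             hysterectomy = rep_len(hysterectomy, n),
             hyst_months_ago = rep_len(as.integer(hyst_months_ago), n),
             unmet_need = rep_len(unmet_need, n),
             state = rep_len(state, n), region = rep_len(region, n),
             residence = rep_len(residence, n),
             education = rep_len(education, n),
             wealth = rep_len(wealth, n), caste = rep_len(caste, n),
             stringsAsFactors = FALSE)
}

# quick cohort small enough for fast tests
small_cohort <- function(n = 2000, seed = 101, ...) {
  generate_cohort(cohort_params(n_women = n, seed = seed, ...))
}
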