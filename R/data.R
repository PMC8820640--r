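# Accessors for the published India 2015-16 reference tables shipped as
# plain-text under inst/extdata. These carry the printed two-decimal values
# and are used for verification against the published application, not as
# model inputs.

#' Published national and state decomposition table, India 2015-16
#'
#' The printed indices (Cm, Cc, Ca, Ci), actual and predicted TFR,
#' residual, percent contributions and unweighted sample sizes for the
#' nation and the 29 states, grouped by major region. Values are as
#' printed (indices and TFRs to two decimals, shares to one).
#'
#' @return Data frame with one row per population (national first).
#' @export
india_pd_table1 <- function() {
  utils::read.csv(system.file("extdata", "table1_india_2016.csv",
                              package = "pdfert", mustWork = TRUE),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published age-group decomposition and ASFRs, India 2015-16
#'
#' Percent contributions by five-year age group, the actual age-specific
#' fertility rates (per 1000 women) and unweighted sample sizes.
#'
#' @return Data frame with 7 rows.
#' @export
india_pd_table2 <- function() {
  utils::read.csv(system.file("extdata", "table2_age_india_2016.csv",
                              package = "pdfert", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published abortion rates, India 2015
#'
#' The abortion incidence rates (per 1000 women 15-49) printed in the text:
#' the national rate and the two state rates quoted as the range of the six
#' study states. The source study also reports regional rates and rates for
#' four further states not reproduced in the text; supply those via
#' [abortion_inputs()] when available.
#'
#' @return A `pd_abortion` object.
#' @export
india_abortion_rates_2015 <- function() {
  read_abortion_inputs(system.file("extdata", "abortion_rates_2015.csv",
                                   package = "pdfert", mustWork = TRUE))
}
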