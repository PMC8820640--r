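#' Microdata column dictionary
#'
#' The delimited-text layout shared by real and synthetic inputs. One row
#' per woman, header first; comma-separated by default, tab accepted.
#' Columns:
#'
#' * `weight` — positive sampling weight
#' * `age` — completed years, 15-49
#' * `currently_married` — 0/1
#' * `method` — current contraceptive method: one of `none`,
#'   `sterilization`, `IUD`, `pill`, `injectable`, `condom`, `traditional`,
#'   `other`; `none` for all unmarried women
#' * `birth_months` — months before interview of each birth in the last 36
#'   months, semicolon-separated integers (empty if none)
#' * `bf_months`, `amen_months`, `abst_months` — completed months of full
#'   breastfeeding / postpartum amenorrhea / postpartum abstinence since the
#'   most recent birth, 0-36; 0 for women without a recent birth
#' * `hysterectomy` — 0/1, non-contraceptive hysterectomy in last 36 months
#' * `hyst_months_ago` — months since that hysterectomy (blank if none)
#' * `unmet_need` — 0/1
#' * `state`, `region`, `residence`, `education`, `wealth`, `caste` —
#'   stratifiers; `residence`, `education`, `wealth` and `caste` are closed
#'   category sets
#'
#' @param residence,education,wealth,caste Allowed categories for the closed
#'   stratifiers (overridable to match a different survey's coding).
#' @return An object of class `pd_schema`.
#' @export
microdata_schema <- function(residence = c("urban", "rural"),
                             education = c("<5", "5-9", "10+"),
                             wealth = c("poor", "middle", "rich"),
                             caste = c("SC/ST", "OBC", "Other")) {
  structure(list(
    columns = c("weight", "age", "currently_married", "method",
                "birth_months", "bf_months", "amen_months", "abst_months",
                "hysterectomy", "hyst_months_ago", "unmet_need",
                "state", "region", "residence", "education", "wealth",
                "caste"),
    methods = c("none", "sterilization", "IUD", "pill", "injectable",
                "condom", "traditional", "other"),
    categories = list(residence = residence, education = education,
                      wealth = wealth, caste = caste)),
    class = "pd_schema")
}

#' Write a cohort to delimited text
#'
#' @param records Microdata data frame (as produced by [generate_cohort()]
#'   or [read_microdata()]).
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path, sep = ",") {
  out <- records
  for (nm in c("currently_married", "hysterectomy", "unmet_need"))
    out[[nm]] <- as.integer(out[[nm]])
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate woman-level microdata
#'
#' Reads delimited text against the [microdata_schema()] column dictionary.
#' Rows violating record-level invariants (age outside 15-49, probability
#' flags not 0/1, a method other than `none` for an unmarried woman,
#' durations outside 0-36 or exceeding the months since the most recent
#' birth, unknown method or stratifier category) are rejected with
#' row-indexed diagnostics and dropped; the retained records are returned
#' with the rejection log in attribute `"rejections"`.
#'
#' A missing required column is a schema error and aborts the read.
#'
#' @param path Input file.
#' @param schema A `pd_schema`; defaults to [microdata_schema()].
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return Data frame of valid records; attributes `rejections` (data frame
#'   of `row`, `reason`) and `n_rejected`.
#' @export
read_microdata <- function(path, schema = microdata_schema(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "",
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(schema$columns, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[schema$columns]
  if (nrow(raw) == 0) {
    empty <- empty_microdata()
    attr(empty, "rejections") <- data.frame(row = integer(),
                                            reason = character())
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  d <- data.frame(
    weight = num(raw$weight),
    age = num(raw$age),
    currently_married = num(raw$currently_married),
    method = raw$method,
    birth_months = ifelse(is.na(raw$birth_months), "", raw$birth_months),
    bf_months = num(raw$bf_months),
    amen_months = num(raw$amen_months),
    abst_months = num(raw$abst_months),
    hysterectomy = num(raw$hysterectomy),
    hyst_months_ago = num(raw$hyst_months_ago),
    unmet_need = num(raw$unmet_need),
    state = raw$state, region = raw$region, residence = raw$residence,
    education = raw$education, wealth = raw$wealth, caste = raw$caste,
    stringsAsFactors = FALSE)

  reasons <- vector("list", nrow(d))
  add <- function(bad, msg) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  flag01 <- function(x) is.na(x) | !(x %in% c(0, 1))
  last_birth <- months_since_last_birth(d)

  add(is.na(d$weight) | d$weight <= 0, "non-positive or missing weight")
  add(is.na(d$age) | d$age < 15 | d$age > 49 | d$age != floor(d$age),
      "age outside [15, 49]")
  add(flag01(d$currently_married), "currently_married not 0/1")
  add(flag01(d$hysterectomy), "hysterectomy not 0/1")
  add(flag01(d$unmet_need), "unmet_need not 0/1")
  add(!(d$method %in% schema$methods), "unknown method")
  add(!is.na(d$currently_married) & d$currently_married == 0 &
        d$method != "none" & d$method %in% schema$methods,
      "method reported for unmarried woman")
  bad_bm <- !grepl("^$|^[0-9]+(;[0-9]+)*$", d$birth_months)
  add(bad_bm, "malformed birth_months")
  add(!bad_bm & !is.na(last_birth) & (last_birth < 1 | last_birth > 36),
      "birth outside 36-month window")
  for (nm in c("bf_months", "amen_months", "abst_months")) {
    add(is.na(d[[nm]]) | d[[nm]] < 0 | d[[nm]] > 36,
        paste(nm, "outside [0, 36]"))
    add(!is.na(d[[nm]]) & !is.na(last_birth) & d[[nm]] > last_birth,
        paste(nm, "exceeds months since last birth"))
    add(!is.na(d[[nm]]) & is.na(last_birth) & d[[nm]] > 0,
        paste(nm, "positive without a recent birth"))
  }
  add(!is.na(d$hysterectomy) & d$hysterectomy == 1 &
        (is.na(d$hyst_months_ago) | d$hyst_months_ago < 0 |
           d$hyst_months_ago > 36),
      "hysterectomy flagged without months in [0, 36]")
  for (nm in names(schema$categories))
    add(is.na(d[[nm]]) | !(d[[nm]] %in% schema$categories[[nm]]),
        paste("unknown", nm, "category"))
  add(is.na(d$state), "missing state")
  add(is.na(d$region), "missing region")

  bad <- !vapply(reasons, is.null, logical(1))
  rejections <- data.frame(
    row = which(bad),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)
  if (nrow(rejections) > 0)
    message(nrow(rejections), " record(s) rejected; see attr(x, 'rejections')")

  keep <- d[!bad, , drop = FALSE]
  keep$currently_married <- keep$currently_married == 1
  keep$hysterectomy <- keep$hysterectomy == 1
  keep$unmet_need <- keep$unmet_need == 1
  keep$age <- as.integer(keep$age)
  for (nm in c("bf_months", "amen_months", "abst_months"))
    keep[[nm]] <- as.integer(keep[[nm]])
  keep$hyst_months_ago <- as.integer(keep$hyst_months_ago)
  rownames(keep) <- NULL
  attr(keep, "rejections") <- rejections
  attr(keep, "n_rejected") <- nrow(rejections)
  keep
}

empty_microdata <- function() {
  data.frame(weight = numeric(), age = integer(),
             currently_married = logical(), method = character(),
             birth_months = character(), bf_months = integer(),
             amen_months = integer(), abst_months = integer(),
             hysterectomy = logical(), hyst_months_ago = integer(),
             unmet_need = logical(), state = character(),
             region = character(), residence = character(),
             education = character(), wealth = character(),
             caste = character(), stringsAsFactors = FALSE)
}

#' Months since the most recent birth
#'
#' @param records Microdata data frame.
#' @return Integer vector; `NA` for women with no birth in the window.
#' @export
months_since_last_birth <- function(records) {
  vapply(records$birth_months, function(s) {
    if (is.na(s) || s == "") return(NA_integer_)
    min(as.integer(strsplit(s, ";", fixed = TRUE)[[1]]))
  }, integer(1), USE.NAMES = FALSE)
}

# list of integer birth-month vectors, one per record
.birth_month_list <- function(records) {
  lapply(records$birth_months, function(s) {
    if (is.na(s) || s == "") integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}
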