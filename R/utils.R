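# Seed substreams: every stochastic stage draws its seed deterministically
# from the master seed plus a label, so stages can be re-run in isolation.
substream_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate expr with a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Demographic design columns (no intercept): age + sex + race dummies.
# These controls are carried, unpenalized and non-eliminable, through every
# regression of the selection and validity stages.
design_demographics <- function(data) {
  stopifnot(all(c("age", "sex", "race_ethnicity") %in% names(data)))
  sex <- factor(data$sex)
  race <- factor(data$race_ethnicity)
  out <- cbind(age = as.numeric(data$age))
  if (nlevels(sex) > 1) {
    for (lv in levels(sex)[-1]) {
      out <- cbind(out, as.numeric(sex == lv))
      colnames(out)[ncol(out)] <- paste0("sex_", lv)
    }
  }
  if (nlevels(race) > 1) {
    for (lv in levels(race)[-1]) {
      out <- cbind(out, as.numeric(race == lv))
      colnames(out)[ncol(out)] <- paste0("race_", lv)
    }
  }
  out
}

component_columns <- function(data) {
  grep("^comp_", names(data), value = TRUE)
}

scale_wave_columns <- function(data, scale) {
  grep(paste0("^", scale, "_w\\d+$"), names(data), value = TRUE)
}
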