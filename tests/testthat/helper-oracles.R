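# Independent oracles and record fixtures shared across test files.

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, point probabilities from binomial coefficients (not dhyper).
fisher_brute <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  if (n == 0) return(1)
  a <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  p_obs <- p[a == m[1, 1]]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Textbook balanced two-way decomposition: cell-mean formulas, F ratios
# against the within-cell mean square.
anova_balanced_oracle <- function(value, a, b) {
  a <- factor(a); b <- factor(b)
  la <- nlevels(a); lb <- nlevels(b)
  r <- length(value) / (la * lb)
  g <- mean(value)
  ma <- tapply(value, a, mean)
  mb <- tapply(value, b, mean)
  mab <- tapply(value, list(a, b), mean)
  ss_a <- lb * r * sum((ma - g)^2)
  ss_b <- la * r * sum((mb - g)^2)
  ss_ab <- r * sum((mab - outer(ma - g, mb - g, "+") - g)^2)
  ss_e <- sum((value - mab[cbind(a, b)])^2)
  df_e <- la * lb * (r - 1)
  mse <- ss_e / df_e
  list(
    F = c(a = (ss_a / (la - 1)) / mse,
          b = (ss_b / (lb - 1)) / mse,
          ab = (ss_ab / ((la - 1) * (lb - 1))) / mse),
    df = c(a = la - 1, b = lb - 1, ab = (la - 1) * (lb - 1), e = df_e)
  )
}

# A clinical-trial record satisfying all 17 criteria.
full_positive_record <- function(id = "full1") {
  new_records(
    id, "CIRCULATION", "CLINICAL_TRIAL",
    study_type_stated = TRUE,
    materials_statement = "YES_AVAILABLE", materials_mode = "REPOSITORY",
    materials_accessible = "YES",
    data_statement = "YES_AVAILABLE", data_mode = "REPOSITORY",
    data_accessible = "YES", data_documented = "YES", data_complete = "YES",
    scripts_statement = "YES_AVAILABLE", scripts_mode = "REPOSITORY",
    scripts_accessible = "YES",
    prereg_statement = "YES", prereg_accessible = "YES",
    prereg_aspects = "HYPOTHESES;METHODS;ANALYSIS_PLAN",
    protocol_linked = TRUE,
    protocol_aspects = "HYPOTHESES;METHODS;ANALYSIS_PLAN",
    coi_statement = "HAS_COI", funding_statement = "PUBLIC",
    open_access = "YES_OA_BUTTON"
  )
}

# A record with every negative/absent response (satisfies nothing).
all_negative_record <- function(id = "neg1",
                                study_type = "CLINICAL_TRIAL") {
  new_records(id, "EHJ", study_type,
              materials_statement = "NO_STATEMENT",
              data_statement = "NO_STATEMENT",
              scripts_statement = "NO_STATEMENT")
}

# Records whose resource-availability pattern is given explicitly; used to
# drive the battery with known contingency tables.
records_with_pattern <- function(study_type, n_yes, n_total, resource,
                                 journal = "JACC", prefix = study_type) {
  rec <- new_records(sprintf("%s%04d", prefix, seq_len(n_total)),
                     journal, study_type)
  yes <- seq_len(n_yes)
  if (resource == "methods") {
    rec$protocol_linked[yes] <- TRUE
  } else {
    rec[[paste0(resource, "_statement")]][yes] <- "YES_AVAILABLE"
    rec[[paste0(resource, "_mode")]][yes] <- "UPON_REQUEST"
    rec[[paste0(resource, "_accessible")]][yes] <- "NO"
  }
  rec$materials_statement[rec$materials_statement == "NOT_APPLICABLE"] <-
    if (study_type %in% c("META_ANALYSIS_SYSTEMATIC_REVIEW",
                          "NONCLINICAL_SECONDARY_DATA")) "NOT_APPLICABLE"
    else "NO_STATEMENT"
  rec
}
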