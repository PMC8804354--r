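# Longitudinal PK dataset: a NONMEM-style event table with censoring flags
# and covariates. CMT 1 = oral depot (doses), 2 = parent observation,
# 3 = metabolite observation.

DATASET_REQUIRED <- c("ID", "TIME", "AMT", "EVID", "CMT", "DV", "MDV", "BLQ", "LLOQ")
DATASET_COVARIATES <- c("WT", "HT", "BMI", "BSA", "AGE", "ALB", "SCR", "ALT",
                        "AST", "TBIL", "EGFR", "OBESE", "SEX", "ADOL")

#' Construct / validate a PK dataset
#'
#' @param df data.frame with the NONMEM-style columns `ID`, `TIME`, `AMT`,
#'   `EVID` (1 dose, 0 observation), `CMT` (1 depot, 2 parent, 3 metabolite),
#'   `DV` (ng/mL; NA for dose rows and censored rows), `MDV`, `BLQ`, `LLOQ`,
#'   plus optional covariate columns (`WT`, `HT`, `BMI`, `BSA`, `AGE`, `ALB`,
#'   `SCR`, `ALT`, `AST`, `TBIL`, `EGFR`, `OBESE`, `SEX`, `ADOL`)
#' @return the validated data.frame with class `pk_dataset`
#' @export
pk_dataset <- function(df) {
  missing_cols <- setdiff(DATASET_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- function(i) paste(utils::head(i, 5), collapse = ", ")
  bad <- which(!df$EVID %in% c(0, 1))
  if (length(bad)) stop("EVID must be 0 or 1; offending row(s): ", rows(bad))
  bad <- which(df$EVID == 1 & (is.na(df$AMT) | df$AMT <= 0))
  if (length(bad)) stop("dose rows need AMT > 0; offending row(s): ", rows(bad))
  bad <- which(df$EVID == 0 & !df$CMT %in% c(2, 3))
  if (length(bad)) {
    stop("observation rows must have CMT 2 (parent) or 3 (metabolite); row(s): ",
         rows(bad))
  }
  bad <- which(df$EVID == 0 & df$BLQ == 1 & is.na(df$LLOQ))
  if (length(bad)) stop("censored rows must carry LLOQ; offending row(s): ", rows(bad))
  bad <- which(df$EVID == 0 & df$BLQ == 0 & (is.na(df$DV) | df$DV < 0))
  if (length(bad)) {
    stop("uncensored observations need non-negative DV; offending row(s): ", rows(bad))
  }
  for (id in unique(df$ID)) {
    idx <- which(df$ID == id)
    tt <- df$TIME[idx]
    if (is.unsorted(tt)) {
      stop("times are not sorted within subject ", id, "; first offending row: ",
           idx[which(diff(tt) < 0)[1] + 1])
    }
    dose_idx <- idx[df$EVID[idx] == 1]
    if (!length(dose_idx)) stop("subject ", id, " has no dose event")
    first_dose <- min(df$TIME[dose_idx])
    early <- idx[df$EVID[idx] == 0 & df$TIME[idx] < first_dose]
    if (length(early)) {
      stop("subject ", id, " has observation(s) before the first dose; row(s): ",
           rows(early))
    }
  }
  structure(as.data.frame(df), class = c("pk_dataset", "data.frame"))
}

#' Read / write the PK dataset CSV dialect
#'
#' Plain CSV with a header; missing covariates as blank fields.
#'
#' @param path file path
#' @return `read_pk_dataset` returns a validated [pk_dataset()];
#'   `write_pk_dataset` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pk_dataset(utils::read.csv(path))
}

#' @rdname read_pk_dataset
#' @param ds a [pk_dataset()]
#' @export
write_pk_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

# Internal: split a dataset into per-subject lists consumed by the C++ core.
split_subjects <- function(ds) {
  lapply(split(as.data.frame(ds), ds$ID), function(d) {
    dose <- d[d$EVID == 1, ]
    obs <- d[d$EVID == 0, ]
    covs <- as.list(d[1, intersect(DATASET_COVARIATES, names(d)), drop = FALSE])
    list(id = d$ID[1],
         dose_t = dose$TIME, dose_amt = dose$AMT,
         obs_t = obs$TIME,
         obs_y = ifelse(is.na(obs$DV), 0, obs$DV),
         obs_analyte = as.integer(ifelse(obs$CMT == 2, 1L, 2L)),
         obs_bql = as.integer(obs$BLQ),
         obs_lloq = ifelse(is.na(obs$LLOQ), 0, obs$LLOQ),
         covariates = covs)
  })
}

# Internal: drop one analyte's observation rows (doses kept).
filter_analyte <- function(ds, analyte = c("both", "parent", "metabolite")) {
  analyte <- match.arg(analyte)
  if (analyte == "both") return(ds)
  keep_cmt <- if (analyte == "parent") 2 else 3
  keep <- ds$EVID == 1 | ds$CMT == keep_cmt
  pk_dataset(as.data.frame(ds)[keep, , drop = FALSE])
}
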