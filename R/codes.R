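#' Canonicalize ICD-10 codes
#'
#' Uppercases and strips dots and whitespace so that "n17.0", "N17 0" and
#' "N170" all compare equal.
#'
#' @param codes Character vector of raw diagnosis codes.
#' @return Canonical character vector.
#' @export
canonicalize_code <- function(codes) {
  toupper(gsub("[. ]", "", trimws(codes)))
}

#' Coding algorithms evaluated by the package
#' @return Character vector of algorithm names.
#' @export
coding_algorithms <- function() {
  c("any_diagnosis", "admission_diagnosis", "main_diagnosis")
}

#' Is an admission code-positive under a coding algorithm?
#'
#' The target code family (default ICD-10 N17x, "acute renal failure") is
#' matched by prefix on canonicalized codes, so N17, N170, ..., N179 all
#' count while N18x (chronic kidney disease) does not. Algorithms:
#'
#' * `any_diagnosis`: the code appears in any of the (up to 25) diagnosis
#'   fields, regardless of diagnosis type;
#' * `admission_diagnosis`: the code appears with diagnosis type `PREADMIT`
#'   (a condition present before admission and treated during the stay);
#' * `main_diagnosis`: the unique most-responsible diagnosis (type `M`)
#'   matches the code.
#'
#' @param codes Character vector of diagnosis codes for one admission.
#' @param dx_types Parallel character vector of diagnosis types
#'   (`"M"`, `"PREADMIT"`, `"OTHER"`).
#' @param algorithm One of [coding_algorithms()].
#' @param prefix Target code prefix, default `"N17"`.
#' @return Logical scalar.
#' @export
code_positive <- function(codes, dx_types, algorithm = coding_algorithms(),
                          prefix = "N17") {
  algorithm <- match.arg(algorithm)
  stopifnot(length(codes) == length(dx_types), nzchar(prefix))
  if (sum(dx_types == "M") > 1) {
    stop("data integrity: more than one most-responsible (type M) diagnosis")
  }
  hit <- startsWith(canonicalize_code(codes), canonicalize_code(prefix))
  switch(algorithm,
    any_diagnosis = any(hit),
    admission_diagnosis = any(hit & dx_types == "PREADMIT"),
    main_diagnosis = any(hit & dx_types == "M")
  )
}

#' Classify all admissions under all coding algorithms
#'
#' @param diagnoses Diagnosis table (`admission_id`, `position`, `code`,
#'   `dx_type`).
#' @param admission_ids Admissions to classify (admissions with no diagnosis
#'   rows are code-negative everywhere).
#' @param prefix Target code prefix, default `"N17"`.
#' @return Data frame: `admission_id` plus one logical column per algorithm.
#' @export
classify_admissions <- function(diagnoses, admission_ids, prefix = "N17") {
  n <- length(admission_ids)
  idx <- match(diagnoses$admission_id, admission_ids)
  dx <- diagnoses[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  n_main <- tabulate(idx[dx$dx_type == "M"], nbins = n)
  if (any(n_main > 1)) {
    stop("data integrity: more than one most-responsible (type M) diagnosis ",
         "in admission ", admission_ids[which(n_main > 1)[1]])
  }
  hit <- startsWith(canonicalize_code(dx$code), canonicalize_code(prefix))
  data.frame(
    admission_id = admission_ids,
    any_diagnosis = tabulate(idx[hit], nbins = n) > 0,
    admission_diagnosis =
      tabulate(idx[hit & dx$dx_type == "PREADMIT"], nbins = n) > 0,
    main_diagnosis = tabulate(idx[hit & dx$dx_type == "M"], nbins = n) > 0,
    stringsAsFactors = FALSE
  )
}
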