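#' Default code-list configuration
#'
#' Returns the code-list configuration used by the phenotyper: ICD-10 prefix
#' sets for the code-based organ-dysfunction categories, comorbidity
#' categories, infection foci, and the identifier sets for intravenous
#' antibiotic and vasopressor agents.
#'
#' The ICD-10 prefixes shipped here are clinically plausible *placeholder*
#' defaults (e.g. K72 hepatic failure, D69.5 secondary thrombocytopenia,
#' D65 disseminated intravascular coagulation, E87.2 acidosis). Production
#' use against a real claims extract should replace them with the locally
#' validated lists via [read_code_lists()].
#'
#' @param matching `"prefix"` (default, standard claims practice: "K72"
#'   matches "K720") or `"exact"`.
#' @return A list with class `code_lists`: elements `dysfunction`,
#'   `comorbidity`, `infection_focus` (each a named list of ICD-10 prefix
#'   character vectors), `antibiotics` and `vasopressors` (character vectors
#'   of agent identifiers), and `matching`.
#' @export
default_code_lists <- function(matching = c("prefix", "exact")) {
  matching <- match.arg(matching)
  cl <- list(
    dysfunction = list(
      hepatic          = c("K72"),
      thrombocytopenia = c("D695", "D696"),
      coagulopathy     = c("D65"),
      acidosis         = c("E872")
    ),
    comorbidity = list(
      hypertension        = c("I10", "I11", "I12", "I13", "I15"),
      diabetes            = c("E10", "E11", "E12", "E13", "E14"),
      malignancy          = c("C"),
      ischemic_heart      = c("I20", "I21", "I22", "I24", "I25"),
      heart_failure       = c("I50"),
      chronic_respiratory = c("J44", "J47", "J84", "J96"),
      cerebrovascular     = c("I60", "I61", "I62", "I63", "I69"),
      chronic_renal       = c("N18", "N19")
    ),
    infection_focus = list(
      respiratory     = c("J12", "J13", "J14", "J15", "J18", "J69", "J85"),
      abdominal       = c("K35", "K57", "K65", "K80", "K81", "K83"),
      urogenital      = c("N10", "N30", "N39"),
      bone_soft_tissue = c("L03", "M00", "M86"),
      blood           = c("A40", "A41"),
      other           = c("G00", "I33")
    ),
    antibiotics  = paste0("ABX", sprintf("%02d", 1:8)),
    vasopressors = c("NORAD", "ADR", "DOPA", "VASOP"),
    matching = matching
  )
  class(cl) <- "code_lists"
  cl
}

#' Read / write a code-list configuration
#'
#' Code lists are stored as plain YAML with top-level keys `dysfunction`,
#' `comorbidity`, `infection_focus`, `antibiotics`, `vasopressors` and
#' optionally `matching`.
#'
#' @param path File path.
#' @return `read_code_lists()` returns a validated `code_lists` object;
#'   `write_code_lists()` returns `path` invisibly.
#' @export
read_code_lists <- function(path) {
  if (!file.exists(path)) stop("code list file not found: ", path)
  raw <- yaml::read_yaml(path)
  cl <- list(
    dysfunction     = lapply(raw$dysfunction, as.character),
    comorbidity     = lapply(raw$comorbidity, as.character),
    infection_focus = lapply(raw$infection_focus, as.character),
    antibiotics     = as.character(raw$antibiotics),
    vasopressors    = as.character(raw$vasopressors),
    matching        = if (is.null(raw$matching)) "prefix" else raw$matching
  )
  class(cl) <- "code_lists"
  validate_code_lists(cl)
  cl
}

#' @rdname read_code_lists
#' @param code_lists A `code_lists` object.
#' @export
write_code_lists <- function(code_lists, path) {
  validate_code_lists(code_lists)
  x <- unclass(code_lists)
  yaml::write_yaml(x, path)
  invisible(path)
}

validate_code_lists <- function(cl) {
  needed <- c("hepatic", "thrombocytopenia", "coagulopathy", "acidosis")
  missing <- setdiff(needed, names(cl$dysfunction))
  if (length(missing))
    stop("code_lists: missing dysfunction categories: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(names(cl$dysfunction)) || anyDuplicated(names(cl$comorbidity)))
    stop("code_lists: category names must be unique")
  if (!length(cl$antibiotics)) stop("code_lists: no antibiotic agents defined")
  if (!length(cl$vasopressors)) stop("code_lists: no vasopressor agents defined")
  if (!cl$matching %in% c("prefix", "exact"))
    stop("code_lists: matching must be 'prefix' or 'exact'")
  invisible(cl)
}

#' Match ICD-10 codes against a category's prefix set
#'
#' @param codes Character vector of ICD-10 codes.
#' @param prefixes Character vector of prefixes (or exact codes).
#' @param matching `"prefix"` or `"exact"`.
#' @return Logical vector, `TRUE` where the code belongs to the category.
#' @export
icd10_match <- function(codes, prefixes, matching = "prefix") {
  if (!length(codes)) return(logical(0))
  if (matching == "exact") return(codes %in% prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
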