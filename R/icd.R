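#' Group ICD-10 main-problem codes into MHA categories
#'
#' Maps each ICD-10 code to one of the six visit categories used throughout
#' the package and, for substance-abuse codes, to a substance subgroup.
#' The grouping is:
#' \itemize{
#'   \item substance: F55 and F10--F19, with subgroups alcohol (F10),
#'     opioid (F11), cannabis (F12), multiple substances (F19) and
#'     other (F13--F18 and F55);
#'   \item schizophrenia: F20 excluding F20.4, F21--F25, F28--F29;
#'   \item mood: F30--F34, F39;
#'   \item anxiety: F40--F45, F48;
#'   \item others (behavioural syndromes, personality disorders,
#'     intentional self-harm): F50--F54, F59--F60, F63--F66, F68--F69,
#'     X60--X84;
#'   \item NMHA: every other code.
#' }
#' A code belongs to a range when its three-character root (letter plus two
#' digits) lies in the range, so sub-codes such as "F10.1" map with their
#' root. The single exclusion F20.4 is tested before the F20 inclusion.
#'
#' @param icd_code character vector of ICD-10 codes
#'   (letter, two digits, optional decimal part, e.g. "F10.2").
#' @return data.frame with columns `icd_code`, `category` and
#'   `substance_subgroup` (`"none"` outside the substance category).
#' @examples
#' categorize_icd(c("F11", "F20.4", "X84", "K35"))
#' @export
categorize_icd <- function(icd_code) {
  if (length(icd_code) == 0) stop("no ICD codes supplied")
  code <- toupper(trimws(as.character(icd_code)))
  bad <- is.na(code) | !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]+)?$", code)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(icd_code[bad]), collapse = ", "),
         " (expected letter + two digits, optional decimal part)")
  }
  root <- substr(code, 1, 3)
  letter <- substr(code, 1, 1)
  num <- as.integer(substr(code, 2, 3))

  in_range <- function(lt, lo, hi) letter == lt & num >= lo & num <= hi

  category <- rep("NMHA", length(code))
  subgroup <- rep("none", length(code))

  is_sub <- in_range("F", 10, 19) | root == "F55"
  category[is_sub] <- "substance"
  subgroup[is_sub & root == "F10"] <- "alcohol"
  subgroup[is_sub & root == "F11"] <- "opioid"
  subgroup[is_sub & root == "F12"] <- "cannabis"
  subgroup[is_sub & root == "F19"] <- "multiple"
  subgroup[is_sub & (in_range("F", 13, 18) | root == "F55")] <- "other"

  # F20.4 is excluded from schizophrenia (falls through to NMHA).
  f204 <- root == "F20" & startsWith(substr(code, 5, 5), "4")
  is_scz <- (root == "F20" & !f204) | in_range("F", 21, 25) | in_range("F", 28, 29)
  category[is_scz] <- "schizophrenia"

  category[in_range("F", 30, 34) | root == "F39"] <- "mood"
  category[in_range("F", 40, 45) | root == "F48"] <- "anxiety"
  is_oth <- in_range("F", 50, 54) | in_range("F", 59, 60) |
    in_range("F", 63, 66) | in_range("F", 68, 69) | in_range("X", 60, 84)
  category[is_oth] <- "others"

  data.frame(icd_code = code, category = category,
             substance_subgroup = subgroup, stringsAsFactors = FALSE)
}
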