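#' The built-in compound class catalogue
#'
#' Class composition of the 408-compound kit panel: 11 metabolite classes,
#' split between liquid chromatography (amino acids, biogenic amines; 42
#' compounds) and flow injection analysis (all lipid classes plus the combined
#' hexose signal; 366 compounds).
#'
#' @return A tibble with columns `class`, `measurement_type`, `expected_count`,
#'   `prefix` (used for systematic compound names) and `istd` (the shared
#'   internal-standard identifier for the class).
#' @export
#' @examples
#' panel_classes()
panel_classes <- function() {
  tibble::tribble(
    ~class,                     ~measurement_type, ~expected_count, ~prefix,
    "amino acids",              "LC",               21L,            "AA",
    "biogenic amines",          "LC",               21L,            "BA",
    "hexose",                   "FIA",               1L,            "Hex",
    "acylcarnitines",           "FIA",              55L,            "AC",
    "cholesteryl esters",       "FIA",              14L,            "CE",
    "diglycerides",             "FIA",              18L,            "DG",
    "triglycerides",            "FIA",              42L,            "TG",
    "phosphatidylcholines",     "FIA",             172L,            "PC",
    "lysophosphatidylcholines", "FIA",              24L,            "LPC",
    "sphingomyelins",           "FIA",              31L,            "SM",
    "ceramides",                "FIA",               9L,            "Cer"
  ) %>%
    mutate(istd = paste("ISTD", .data$prefix))
}

# Amino acid and biogenic amine names as reported for this kit generation;
# lipid species are not enumerated publicly, so those get systematic names.
aa_names <- c(
  "Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "xLeu"
)

ba_names <- c(
  "Ac-Orn", "ADMA", "alpha-AAA", "Carnosine", "Creatinine", "DOPA",
  "Dopamine", "Histamine", "Kynurenine", "Met-SO", "Nitro-Tyr", "OH-Pro",
  "Orn", "PEA", "Putrescine", "Sarcosine", "Serotonin", "Spermidine",
  "Spermine", "Taurine", "total-DMA"
)

build_p400_panel <- function() {
  cls <- panel_classes()
  compounds <- purrr::pmap_dfr(cls, function(class, measurement_type,
                                             expected_count, prefix, istd) {
    name <- switch(class,
      "amino acids"     = aa_names,
      "biogenic amines" = ba_names,
      "hexose"          = "Hexoses",
      sprintf("%s %0*d", prefix, nchar(as.character(expected_count)),
              seq_len(expected_count))
    )
    stopifnot(length(name) == expected_count)
    tibble(
      compound = name, class = class,
      measurement_type = measurement_type, istd = istd
    )
  })
  new_panel(compounds)
}

new_panel <- function(compounds) {
  structure(as_tibble(compounds), class = c("plateqc_panel", class(tibble())))
}

#' Load a compound panel
#'
#' A panel is the catalogue of compounds a plate can report: one row per
#' compound with its metabolite class, measurement type (`"LC"` or `"FIA"`)
#' and the identifier of the isotopically labelled internal standard used to
#' normalize it. `load_panel("p400")` returns the built-in 408-compound,
#' 11-class panel; any other `source` is read as a CSV file with columns
#' `name`, `class`, `measurement_type`, `internal_standard_id`.
#'
#' @param source `"p400"` for the built-in panel, or the path to a panel CSV.
#' @return A `plateqc_panel` tibble with columns `compound`, `class`,
#'   `measurement_type`, `istd`.
#' @export
#' @examples
#' panel <- load_panel("p400")
#' nrow(panel)                       # 408
#' class_counts(panel, "LC")         # sums to 42
load_panel <- function(source = "p400") {
  if (identical(source, "p400")) {
    return(build_p400_panel())
  }
  if (!file.exists(source)) {
    abort(sprintf("panel file not found: %s", source))
  }
  raw <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("name", "class", "measurement_type", "internal_standard_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("panel file is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    abort("panel file contains no compounds")
  }
  known <- panel_classes()
  bad_class <- setdiff(unique(raw$class), known$class)
  if (length(bad_class) > 0) {
    abort(sprintf("unknown class label(s) in panel file: %s",
                  paste(bad_class, collapse = ", ")))
  }
  bad_type <- setdiff(unique(raw$measurement_type), c("LC", "FIA"))
  if (length(bad_type) > 0) {
    abort(sprintf("measurement_type must be LC or FIA, got: %s",
                  paste(bad_type, collapse = ", ")))
  }
  dup <- raw$name[duplicated(raw$name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate compound name(s) in panel file: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  new_panel(tibble(
    compound = raw$name, class = raw$class,
    measurement_type = raw$measurement_type, istd = raw$internal_standard_id
  ))
}

#' Count panel compounds per class
#'
#' @param panel A panel, from [load_panel()].
#' @param measurement_type Optional: restrict to `"LC"` or `"FIA"` compounds.
#' @return A tibble with columns `class`, `measurement_type` and `n`; one row
#'   per class present after the restriction (an empty restriction gives zero
#'   rows).
#' @export
#' @examples
#' sum(class_counts(load_panel("p400"), "FIA")$n)   # 366
class_counts <- function(panel, measurement_type = NULL) {
  stopifnot(is.data.frame(panel))
  if (!is.null(measurement_type)) {
    panel <- filter(panel, .data$measurement_type %in% !!measurement_type)
  }
  panel %>%
    count(.data$class, .data$measurement_type, name = "n") %>%
    as_tibble()
}

#' @export
print.plateqc_panel <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<plateqc panel: %d compounds, %d classes (LC %d / FIA %d)>\n",
              nrow(x), nrow(cc),
              sum(cc$n[cc$measurement_type == "LC"]),
              sum(cc$n[cc$measurement_type == "FIA"])))
  NextMethod()
}
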