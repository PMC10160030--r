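## Theoretical m/z for small-metabolite target ions. Negative-mode DESI of
## organic acids is dominated by the singly deprotonated [M-H]- species;
## deprotonation uses the proton mass (not the hydrogen-atom mass), i.e. the
## electron mass stays with the anion -- the standard high-resolution MS
## convention (the alternative differs by ~0.0005 Da, well inside a +/-5 ppm
## window at these masses).

# monoisotopic atomic masses (Da)
.MONOISOTOPIC <- c(
    C  = 12.0,
    H  = 1.00782503,
    N  = 14.00307401,
    O  = 15.99491462,
    P  = 30.97376200,
    S  = 31.97207069,
    Cl = 34.96885268,
    Na = 22.98976928,
    K  = 38.96370649
)

.PROTON_MASS <- 1.00727646

#' Parse a Hill-notation molecular formula
#'
#' Accepts formulas over C, H, N, O, P, S, Cl, Na, K (e.g. `"C4H6O4"`).
#'
#' @param text formula string
#' @return named integer vector, element symbol -> count
#' @examples
#' parseFormula("C4H6O5")  # malate
#' @export
parseFormula <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    if (!nzchar(text)) return(stats::setNames(integer(0), character(0)))
    tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1L]]
    consumed <- sum(attr(tokens, "match.length"))
    if (tokens[1L] == -1L || consumed != nchar(text))
        stop("malformed formula '", text, "'")
    parts <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1L]]
    elements <- sub("[0-9]*$", "", parts)
    counts <- sub("^[A-Za-z]+", "", parts)
    counts <- ifelse(counts == "", 1L, as.integer(counts))
    bad <- setdiff(elements, names(.MONOISOTOPIC))
    if (length(bad)) {
        pos <- regexpr(bad[1L], text)
        stop("unrecognized element symbol '", bad[1L], "' at position ",
             pos, " in formula '", text, "'")
    }
    if (any(counts < 1L))
        stop("element counts must be positive in formula '", text, "'")
    out <- tapply(counts, elements, sum)
    stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition named integer vector as returned by [parseFormula()],
#'   or a formula string
#' @return monoisotopic mass in Da
#' @examples
#' monoisotopicMass("H2O")  # 18.01056
#' @export
monoisotopicMass <- function(composition) {
    if (is.character(composition)) composition <- parseFormula(composition)
    if (!length(composition)) return(0)
    bad <- setdiff(names(composition), names(.MONOISOTOPIC))
    if (length(bad))
        stop("no tabulated monoisotopic mass for: ",
             paste(bad, collapse = ", "))
    sum(.MONOISOTOPIC[names(composition)] * as.numeric(composition))
}

#' Theoretical m/z of an adduct ion
#'
#' Supported negative-mode species: `"[M-H]-"` (deprotonation, M minus one
#' proton), `"[M+Cl]-"` (chloride attachment plus an electron, approximated
#' as M + Cl monoisotopic mass) and `"M-"` (radical anion, M unchanged;
#' electron mass neglected). Singly charged ions are assumed throughout.
#'
#' @param neutralMass neutral monoisotopic mass in Da
#' @param adduct one of `"[M-H]-"`, `"[M+Cl]-"`, `"M-"`
#' @return theoretical m/z in Th
#' @examples
#' adductMz(monoisotopicMass("C4H6O4"), "[M-H]-")  # succinate, 117.0193
#' @export
adductMz <- function(neutralMass, adduct = "[M-H]-") {
    stopifnot(is.numeric(neutralMass), neutralMass > 0)
    switch(adduct,
        "[M-H]-"  = neutralMass - .PROTON_MASS,
        "[M+Cl]-" = neutralMass + .MONOISOTOPIC[["Cl"]],
        "M-"      = neutralMass,
        stop("unsupported adduct '", adduct, "'"))
}

#' Build a metabolite record
#'
#' @param name metabolite name
#' @param formula Hill-notation molecular formula
#' @param adduct adduct species, see [adductMz()]
#' @param verified logical, FALSE flags assignments whose adduct is assumed
#'   rather than confirmed
#' @return one-row data.frame with columns `name`, `formula`, `adduct`,
#'   `neutral_mass`, `theoretical_mz`, `nominal_mz`, `verified`
#' @examples
#' metaboliteRecord("succinate", "C4H6O4")
#' @export
metaboliteRecord <- function(name, formula, adduct = "[M-H]-",
                             verified = TRUE) {
    m <- monoisotopicMass(parseFormula(formula))
    mz <- adductMz(m, adduct)
    data.frame(name = name, formula = formula, adduct = adduct,
               neutral_mass = m, theoretical_mz = mz,
               nominal_mz = as.integer(round(mz)), verified = verified,
               stringsAsFactors = FALSE)
}

#' Read a metabolite registry from delimited text
#'
#' Expects a tab- or comma-separated table with columns `name`, `formula`,
#' `adduct` (optional `verified`); theoretical and nominal m/z are computed.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @return data.frame of metabolite records
#' @seealso [defaultMetaboliteRegistry()]
#' @export
readMetaboliteRegistry <- function(path, sep = "\t") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("name", "formula", "adduct")
    if (!all(need %in% names(tab)))
        stop("registry must have columns: ", paste(need, collapse = ", "))
    if (is.null(tab$verified)) tab$verified <- TRUE
    do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
        metaboliteRecord(tab$name[i], tab$formula[i], tab$adduct[i],
                         as.logical(tab$verified[i]))))
}

#' Default metabolite registry
#'
#' The TCA-cycle intermediates imaged along the root axis (citrate and
#' isocitrate share one entry -- they are isomers and indistinguishable by
#' mass alone) plus quinate, hexose and the benzoxazinoid MBOA, all as
#' [M-H]-. Entries whose adduct assignment is assumed rather than confirmed
#' carry `verified = FALSE`.
#'
#' @return data.frame of metabolite records
#' @examples
#' defaultMetaboliteRegistry()
#' @export
defaultMetaboliteRegistry <- function() {
    readMetaboliteRegistry(system.file("extdata", "metabolites.tsv",
                                       package = "rootMSI", mustWork = TRUE))
}
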