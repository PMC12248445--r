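#' @title Lipid mass database
#' @description Elemental compositions, monoisotopic masses and
#'   negative-mode adduct m/z values for the glycerophospholipid and
#'   sphingomyelin classes profiled by the pipeline (PE, alkyl-ether PE O,
#'   plasmalogen PE P, PI, PS, SM).
#' @name lipid_db
NULL

# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)
.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS

.LIPID_CLASSES <- c("PE", "PE_O", "PE_P", "PI", "PS", "SM")

#' Supported lipid classes
#'
#' @return Character vector of the class codes understood by the package:
#'   diacyl PE, alkyl-ether PE (PE_O), plasmalogen PE (PE_P), PI, PS and SM.
#' @export
lipid_classes <- function() .LIPID_CLASSES

#' Elemental composition of a species-level lipid
#'
#' Builds the full elemental composition (C, H, N, O, P) of a lipid from its
#' class backbone and the total chain carbons/double bonds of its shorthand
#' name (e.g. "PE 38:4" means `total_carbons = 38`, `double_bonds = 4`,
#' head group excluded). For sphingomyelin the d-backbone convention is
#' used, i.e. carbons and double bonds count the sphingoid base plus the
#' N-acyl chain. A plasmalogen PE P c:d is treated as its isobaric
#' alkyl-ether analogue PE O c:(d+1): the vinyl-ether double bond is not
#' counted in the shorthand d.
#'
#' @param lipid_class One of [lipid_classes()].
#' @param total_carbons Integer, total chain carbons (24--48).
#' @param double_bonds Integer, total chain double bonds (0--8).
#' @return Named integer vector over elements C, H, N, O, P (zero counts
#'   dropped).
#' @examples
#' composition_of("PE", 34, 1)  # C39 H76 N O8 P
#' @export
composition_of <- function(lipid_class, total_carbons, double_bonds) {
  lipid_class <- as.character(lipid_class)
  if (!lipid_class %in% .LIPID_CLASSES) {
    stop("unsupported lipid class: ", lipid_class, call. = FALSE)
  }
  c <- as.integer(total_carbons)
  d <- as.integer(double_bonds)
  if (is.na(c) || c < 24L || c > 48L) {
    stop("total_carbons out of supported range 24-48: ", total_carbons,
         call. = FALSE)
  }
  if (is.na(d) || d < 0L || d > 8L) {
    stop("double_bonds out of supported range 0-8: ", double_bonds,
         call. = FALSE)
  }
  comp <- switch(lipid_class,
    PE   = c(C = c + 5L, H = 2L * c + 10L - 2L * d, N = 1L, O = 8L,  P = 1L),
    PS   = c(C = c + 6L, H = 2L * c + 10L - 2L * d, N = 1L, O = 10L, P = 1L),
    PI   = c(C = c + 9L, H = 2L * c + 15L - 2L * d,          O = 13L, P = 1L),
    PE_O = c(C = c + 5L, H = 2L * c + 12L - 2L * d, N = 1L, O = 7L,  P = 1L),
    # plasmalogen: isobar of the alkyl ether with one more double bond
    PE_P = composition_of("PE_O", c, d + 1L),
    SM   = c(C = c + 5L, H = 2L * c + 13L - 2L * d, N = 2L, O = 6L,  P = 1L)
  )
  if (comp[["H"]] <= 0L) {
    stop("invalid chain: non-positive hydrogen count for ", lipid_class,
         " ", c, ":", d, call. = FALSE)
  }
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named numeric vector of element counts over
#'   C, H, N, O, P.
#' @return Mass in Da. An empty composition has mass 0.
#' @examples
#' monoisotopic_mass(composition_of("PI", 38, 4))  # 886.5571
#' @export
monoisotopic_mass <- function(composition) {
  if (length(composition) == 0) return(0.0)
  el <- names(composition)
  unknown <- setdiff(el, names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(as.numeric(composition) * .ATOMIC_MASS[el])
}

#' Negative-mode adduct table
#'
#' The adducts the panel considers in negative-ion mode. Glycerophospholipids
#' with an exchangeable proton (PE, PE O, PE P, PI, PS) are detected
#' deprotonated; zwitterionic SM (quaternary amine, no acidic proton) is
#' detected as an acetate adduct by default, with chloride and demethylated
#' (loss of a choline methyl) forms selectable. Mass deltas are signed,
#' applied to the neutral monoisotopic mass, and include the electron so the
#' result is a true singly charged anion m/z.
#'
#' @return data.frame with columns `adduct`, `mass_delta` (Da) and
#'   `applicable_classes` (comma-separated class codes).
#' @export
adduct_table <- function() {
  glycero <- "PE,PE_O,PE_P,PI,PS"
  data.frame(
    adduct = c("deprotonated", "acetate", "chloride", "demethylated"),
    mass_delta = c(
      -.PROTON_MASS,
      monoisotopic_mass(c(C = 2, H = 3, O = 2)) + .ELECTRON_MASS,
      34.96885268 + .ELECTRON_MASS,
      -monoisotopic_mass(c(C = 1, H = 3)) + .ELECTRON_MASS
    ),
    applicable_classes = c(glycero, "SM", "SM", "SM"),
    stringsAsFactors = FALSE
  )
}

.adduct_applies <- function(adduct_row, lipid_class) {
  lipid_class %in% strsplit(adduct_row$applicable_classes, ",")[[1]]
}

#' Adduct m/z of a lipid species
#'
#' @param lipid_class,total_carbons,double_bonds Species identity as in
#'   [composition_of()].
#' @param adduct Adduct name from [adduct_table()].
#' @return Singly charged negative-ion m/z in Da.
#' @examples
#' adduct_mz("PI", 38, 4, "deprotonated")  # 885.5499
#' @export
adduct_mz <- function(lipid_class, total_carbons, double_bonds,
                      adduct = "deprotonated") {
  tab <- adduct_table()
  row <- tab[tab$adduct == adduct, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown adduct: ", adduct, call. = FALSE)
  if (!.adduct_applies(row, lipid_class)) {
    stop("adduct '", adduct, "' not applicable to class ", lipid_class,
         call. = FALSE)
  }
  monoisotopic_mass(composition_of(lipid_class, total_carbons, double_bonds)) +
    row$mass_delta
}

#' Species shorthand label
#'
#' "PI 38:4", "PE P 38:6" (class code with the underscore replaced by a
#' space) or "SM d34:1" for the sphingoid d-backbone convention.
#'
#' @param lipid_class,total_carbons,double_bonds Species identity.
#' @return Character label.
#' @export
species_label <- function(lipid_class, total_carbons, double_bonds) {
  n <- max(length(lipid_class), length(total_carbons), length(double_bonds))
  lipid_class <- rep_len(lipid_class, n)
  cd <- paste0(rep_len(total_carbons, n), ":", rep_len(double_bonds, n))
  ifelse(lipid_class == "SM", paste0("SM d", cd),
         paste(gsub("_", " ", lipid_class), cd))
}

# species (class, carbons, double bonds) triples observed in bronchial
# biopsies in negative mode; minor species completing each class are part
# of the simulator's assumed ground truth
.PANEL_SPECIES <- local({
  x <- rbind(
    data.frame(lipid_class = "PI",
               total_carbons = c(32, 34, 34, 36, 36, 36, 38, 38),
               double_bonds  = c(0, 1, 2, 1, 2, 4, 3, 4)),
    data.frame(lipid_class = "PE",
               total_carbons = c(36, 36, 36, 38, 38, 38, 40),
               double_bonds  = c(1, 2, 4, 2, 4, 6, 6)),
    data.frame(lipid_class = "PE_P",
               total_carbons = c(36, 38, 38, 40),
               double_bonds  = c(1, 4, 6, 6)),
    data.frame(lipid_class = "PS",
               total_carbons = c(36, 38, 40),
               double_bonds  = c(1, 4, 6)),
    data.frame(lipid_class = "SM",
               total_carbons = c(34, 36, 42, 42),
               double_bonds  = c(1, 1, 1, 2))
  )
  x
})

.formula_string <- function(composition) {
  composition <- composition[composition > 0]
  paste0(names(composition),
         ifelse(composition == 1, "", composition), collapse = "")
}

#' Default annotation panel
#'
#' The species-level panel used throughout the pipeline: every PI, PE,
#' PE P, PS and SM species profiled in bronchial biopsy sections, each with
#' its default negative-mode adduct and theoretical m/z, sorted by m/z. All
#' entries fall inside the 550--1000 Da acquisition window.
#'
#' Plasmalogen entries are reported as PE P; the isobaric alkyl-ether
#' alternative (PE O with one more double bond) is carried in the
#' `isobar_alternative` column so the assignment convention stays auditable.
#'
#' @param sm_adduct Adduct used for sphingomyelin: "acetate" (default),
#'   "chloride" or "demethylated".
#' @return data.frame with columns `lipid_class`, `total_carbons`,
#'   `double_bonds`, `species`, `adduct`, `formula`, `neutral_mass`,
#'   `mz_theoretical`, `isobar_alternative`.
#' @examples
#' head(default_panel())
#' @export
default_panel <- function(sm_adduct = c("acetate", "chloride", "demethylated")) {
  sm_adduct <- match.arg(sm_adduct)
  sp <- .PANEL_SPECIES
  sp$adduct <- ifelse(sp$lipid_class == "SM", sm_adduct, "deprotonated")
  comp <- Map(composition_of, sp$lipid_class, sp$total_carbons,
              sp$double_bonds)
  sp$species <- species_label(sp$lipid_class, sp$total_carbons,
                              sp$double_bonds)
  sp$formula <- vapply(comp, .formula_string, character(1))
  sp$neutral_mass <- vapply(comp, monoisotopic_mass, numeric(1))
  sp$mz_theoretical <- mapply(adduct_mz, sp$lipid_class, sp$total_carbons,
                              sp$double_bonds, sp$adduct)
  sp$isobar_alternative <- ifelse(
    sp$lipid_class == "PE_P",
    species_label("PE_O", sp$total_carbons, sp$double_bonds + 1L),
    NA_character_
  )
  sp <- sp[order(sp$mz_theoretical), , drop = FALSE]
  rownames(sp) <- NULL
  stopifnot(all(sp$mz_theoretical >= 550), all(sp$mz_theoretical <= 1000))
  sp
}

#' Write / read a panel as TSV
#'
#' @param panel data.frame as returned by [default_panel()].
#' @param path File path.
#' @return `read_panel()` returns the panel data.frame; `write_panel()`
#'   returns `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
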