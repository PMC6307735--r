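#' Carbon atom maps for the glycolysis/TCA-cycle label network
#'
#' An atom map records, for one reaction, which substrate carbon ends up in
#' which product carbon, plus any carbons lost as CO2. The registry below is
#' the complete set of transfers used by [propagate()]: glycolytic cleavage
#' (with the C1/C6 symmetry of fructose-1,6-bisphosphate, so glucose C1 labels
#' only half of the pyruvate C3 pool), pyruvate dehydrogenase, pyruvate
#' carboxylase, citrate synthase through alpha-ketoglutarate, the symmetric
#' succinate/fumarate segment, malic enzyme, and the exchange reactions that
#' write the profile out to lactate, alanine, glutamate and glutamine.
#'
#' @param reaction Reaction name (character scalar).
#' @param transfers Data frame with columns `from_met`, `from_carbon`,
#'   `to_met`, `to_carbon`, `weight`. `weight` is the fraction of the product
#'   carbon drawn from that source carbon (used for the glycolytic C1/C6
#'   split); weights for a given product carbon must sum to at most 1, the
#'   remainder being unlabeled carbon (e.g. CO2 fixed by pyruvate carboxylase).
#' @param co2_loss Character vector of `"met Cn"` labels lost as CO2.
#'
#' @return An object of class `atom_map`.
#' @seealso [atom_map_registry()], [write_atom_maps()]
#' @export
atom_map <- function(reaction, transfers, co2_loss = character()) {
  stopifnot(is.character(reaction), length(reaction) == 1L)
  need <- c("from_met", "from_carbon", "to_met", "to_carbon", "weight")
  if (!all(need %in% names(transfers))) {
    stop("transfers must have columns: ", paste(need, collapse = ", "))
  }
  # every product carbon has exactly one row per source; summed source weight <= 1
  key <- paste(transfers$to_met, transfers$to_carbon)
  w <- tapply(transfers$weight, key, sum)
  if (any(w > 1 + 1e-12)) {
    stop("atom map '", reaction, "': source weights for a product carbon exceed 1")
  }
  structure(list(reaction = reaction, transfers = transfers, co2_loss = co2_loss),
            class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat("<atom_map>", x$reaction, "\n")
  tr <- x$transfers
  cat(paste0("  ", tr$from_met, " C", tr$from_carbon, " -> ",
             tr$to_met, " C", tr$to_carbon,
             ifelse(tr$weight < 1, sprintf(" (w=%.2g)", tr$weight), ""),
             collapse = "\n"), "\n")
  if (length(x$co2_loss)) cat("  lost as CO2:", paste(x$co2_loss, collapse = ", "), "\n")
  invisible(x)
}

.tr <- function(...) {
  m <- matrix(c(...), ncol = 5L, byrow = TRUE)
  data.frame(from_met = m[, 1], from_carbon = as.integer(m[, 2]),
             to_met = m[, 3], to_carbon = as.integer(m[, 4]),
             weight = as.numeric(m[, 5]), stringsAsFactors = FALSE)
}

#' Registry of atom maps used by the propagation model
#'
#' @return Named list of [atom_map()] objects.
#' @export
atom_map_registry <- function() {
  list(
    glycolysis = atom_map("glycolysis",
      # F1,6BP cleavage + triose phosphate isomerase: Glc C1 and C6 both feed
      # Pyr C3, so a C1-only tracer labels half the glycolytic Pyr C3 pool.
      .tr("Glc", 1, "Pyr", 3, 0.5,
          "Glc", 6, "Pyr", 3, 0.5,
          "Glc", 2, "Pyr", 2, 0.5,
          "Glc", 5, "Pyr", 2, 0.5)),
    pdh = atom_map("pyruvate dehydrogenase",
      .tr("Pyr", 3, "AcCoA", 2, 1,
          "Pyr", 2, "AcCoA", 1, 1),
      co2_loss = "Pyr C1"),
    acetate_activation = atom_map("acetyl-CoA synthetase",
      .tr("Ace", 2, "AcCoA", 2, 1,
          "Ace", 1, "AcCoA", 1, 1)),
    pc = atom_map("pyruvate carboxylase",
      # CO2 (unlabeled) becomes OAA C4; weight < 1 rows are not needed because
      # tracked OAA carbons 2/3 map one-to-one from pyruvate.
      .tr("Pyr", 2, "OAA", 2, 1,
          "Pyr", 3, "OAA", 3, 1)),
    cs_to_akg = atom_map("citrate synthase to alpha-ketoglutarate",
      # canonical mapping; aKG C1 is lost at succinyl-CoA synthesis
      .tr("OAA", 2, "aKG", 3, 1,
          "OAA", 3, "aKG", 2, 1,
          "AcCoA", 2, "aKG", 4, 1,
          "AcCoA", 1, "aKG", 5, 1),
      co2_loss = "aKG C1"),
    succinate = atom_map("succinyl-CoA to succinate (symmetric)",
      # molecular symmetry of succinate: C2/C3 read both aKG C3 and C4
      .tr("aKG", 3, "Succ", 2, 0.5,
          "aKG", 4, "Succ", 2, 0.5,
          "aKG", 3, "Succ", 3, 0.5,
          "aKG", 4, "Succ", 3, 0.5)),
    fumarase_mdh = atom_map("fumarase + malate dehydrogenase",
      .tr("Succ", 2, "Mal", 2, 1,
          "Succ", 3, "Mal", 3, 1)),
    me = atom_map("malic enzyme",
      .tr("Mal", 2, "Pyr", 2, 1,
          "Mal", 3, "Pyr", 3, 1),
      co2_loss = "Mal C4"),
    ldh = atom_map("lactate dehydrogenase",
      .tr("Pyr", 2, "Lac", 2, 1,
          "Pyr", 3, "Lac", 3, 1)),
    alt = atom_map("alanine aminotransferase",
      .tr("Pyr", 2, "Ala", 2, 1,
          "Pyr", 3, "Ala", 3, 1)),
    glud = atom_map("glutamate dehydrogenase/transaminases",
      .tr("aKG", 2, "Glu", 2, 1,
          "aKG", 3, "Glu", 3, 1,
          "aKG", 4, "Glu", 4, 1)),
    gs = atom_map("glutamine synthetase",
      .tr("Glu", 2, "Gln", 2, 1,
          "Glu", 3, "Gln", 3, 1,
          "Glu", 4, "Gln", 4, 1))
  )
}

#' Serialize the atom-map registry to a plain-text table
#'
#' Writes one row per carbon transfer (reaction, source, destination, weight),
#' followed by CO2 losses, as tab-separated text.
#'
#' @param file Output path.
#' @param registry Registry list, default [atom_map_registry()].
#' @return The table, invisibly.
#' @export
write_atom_maps <- function(file, registry = atom_map_registry()) {
  rows <- do.call(rbind, lapply(registry, function(m) {
    tr <- m$transfers
    data.frame(reaction = m$reaction,
               from = paste0(tr$from_met, " C", tr$from_carbon),
               to = paste0(tr$to_met, " C", tr$to_carbon),
               weight = tr$weight, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
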