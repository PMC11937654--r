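# Unit handling: concentrations are "value unit" strings. Three dimension
# classes exist and may never be mixed between stock and final:
#   molar   : pM, nM, uM (also written with a mu), mM, M   -> normalized to nM
#   enzyme  : U/mL, U/uL                                   -> normalized to U/mL
#   fold    : x / X (buffer fold-concentrates)             -> as-is

.MU <- c("µ", "μ")  # micro sign and Greek mu

parse_conc <- function(x) {
  if (is.list(x)) return(x)
  x <- trimws(as.character(x))
  for (mu in .MU) x <- gsub(mu, "u", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*([A-Za-z/]+)$", x))[[1L]]
  if (length(m) != 3L) stop("cannot parse concentration: '", x, "'")
  value <- as.numeric(m[2L])
  unit <- m[3L]
  tab <- list(
    pM = c("molar", 1e-3), nM = c("molar", 1), uM = c("molar", 1e3),
    mM = c("molar", 1e6), M = c("molar", 1e9),
    `U/mL` = c("enzyme", 1), `U/ml` = c("enzyme", 1), `U/uL` = c("enzyme", 1e3),
    `U/ul` = c("enzyme", 1e3),
    x = c("fold", 1), X = c("fold", 1))
  if (!unit %in% names(tab)) stop("unknown concentration unit: '", unit, "'")
  cls <- tab[[unit]][1L]
  fac <- as.numeric(tab[[unit]][2L])
  if (!is.finite(value) || value <= 0) stop("concentration must be > 0: '", x, "'")
  list(value = value, unit = unit, class = cls, norm = value * fac)
}

round2_half_up <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

#' Volume of stock needed for a target final concentration (C1V1 = C2V2)
#'
#' @param stock,final Concentration strings such as `"10 uM"`, `"100 nM"`,
#'   `"2000 U/mL"`, `"10 x"`. Stock and final must share a dimension class
#'   and satisfy `stock >= final`.
#' @param total Total reaction volume in uL.
#' @return Volume in uL, rounded to 2 decimals (half-up).
#' @examples
#' mix_volume("10 uM", "100 nM", 20)   # 0.2
#' mix_volume("280 mM", "14 mM", 15)   # 0.75
#' @export
mix_volume <- function(stock, final, total) {
  s <- parse_conc(stock); f <- parse_conc(final)
  if (s$class != f$class) {
    stop("incompatible units: '", s$unit, "' vs '", f$unit, "'")
  }
  if (s$norm < f$norm) {
    stop("final concentration (", f$value, " ", f$unit,
         ") exceeds stock (", s$value, " ", s$unit, ")")
  }
  round2_half_up(total * f$norm / s$norm)
}

#' Declare one recipe component
#'
#' @param name Component name.
#' @param stock,final Concentration strings (see [mix_volume()]); omit both
#'   for a fixed-volume component.
#' @param fixed_volume Volume in uL overriding concentration math (e.g. a
#'   "2 uL template" line).
#' @param note Free-text handling note (e.g. "add last, in the tube lid").
#' @return A list of class `recipe_component`.
#' @export
component <- function(name, stock = NULL, final = NULL, fixed_volume = NULL,
                      note = NULL) {
  if (is.null(fixed_volume) && (is.null(stock) || is.null(final))) {
    stop("component '", name,
         "' needs either stock+final concentrations or a fixed_volume")
  }
  structure(list(name = name, stock = stock, final = final,
                 fixed_volume = fixed_volume, note = note),
            class = "recipe_component")
}

#' Build a reaction recipe with water fill
#'
#' Computes each component's per-reaction volume by C1V1 = C2V2 (2-decimal
#' half-up rounding; fixed-volume components taken as given) and fills with
#' water to the total, so that the volumes plus water sum exactly to the
#' total (water absorbs the rounding residue).
#'
#' @param components List of [component()] objects.
#' @param total Total reaction volume in uL.
#' @param replicates Number of reactions to scale the mix for (default 1).
#' @param surplus Fractional surplus of mastermix (e.g. 0.1 for ~10%);
#'   applied together with `replicates` as a pure scaling of the per-reaction
#'   volumes, reported in the `scaled` column.
#' @return `data.frame` of class `reaction_recipe` with columns `reagent`,
#'   `stock`, `final`, `volume` (per reaction, uL), `scaled` (uL for
#'   `replicates` reactions + surplus) and `note`; the water row is last.
#' @examples
#' build_recipe(list(
#'   component("CutSmart Buffer", "10 x", "1 x"),
#'   component("FAM reporter", "10 uM", "100 nM"),
#'   component("crRNA", "10 uM", "50 nM"),
#'   component("EnGen LbCas12a", "10 uM", "40 nM"),
#'   component("target DNA", fixed_volume = 2)), total = 20)
#' @export
build_recipe <- function(components, total, replicates = 1L, surplus = 0) {
  if (inherits(components, "recipe_component")) components <- list(components)
  vols <- vapply(components, function(co) {
    if (!is.null(co$fixed_volume)) as.numeric(co$fixed_volume)
    else mix_volume(co$stock, co$final, total)
  }, numeric(1))
  used <- round2_half_up(sum(vols))
  if (used > total + 1e-9) {
    stop("component volumes (", sprintf("%.2f", used),
         " uL) exceed the total of ", total, " uL by ",
         sprintf("%.2f", used - total), " uL")
  }
  water <- round2_half_up(total - sum(vols))
  scale <- replicates * (1 + surplus)
  out <- data.frame(
    reagent = c(vapply(components, `[[`, character(1), "name"), "Water"),
    stock = c(vapply(components, function(co)
      if (is.null(co$stock)) "-" else as.character(co$stock), character(1)), "-"),
    final = c(vapply(components, function(co)
      if (is.null(co$final)) "-" else as.character(co$final), character(1)), "-"),
    volume = c(vols, water),
    scaled = round2_half_up(c(vols, water) * scale),
    note = c(vapply(components, function(co)
      if (is.null(co$note)) "" else co$note, character(1)), ""),
    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "replicates") <- replicates
  attr(out, "surplus") <- surplus
  class(out) <- c("reaction_recipe", class(out))
  out
}

#' @export
print.reaction_recipe <- function(x, ...) {
  cat("Reaction recipe (", attr(x, "total"), " uL per reaction",
      if (attr(x, "replicates") != 1L || attr(x, "surplus") != 0)
        paste0("; mix for ", attr(x, "replicates"), " reactions + ",
               round(100 * attr(x, "surplus")), "% surplus"),
      ")\n", sep = "")
  df <- data.frame(Reagent = x$reagent, Stock = x$stock, Final = x$final,
                   `uL/rxn` = sprintf("%.2f", x$volume),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Duplex concentration after annealing two complementary oligonucleotides
#'
#' Complementary single-stranded oligos must be mixed in equimolar ratio;
#' the duplex concentration is `stock * volume / total` for either oligo.
#' Molar amounts differing by more than 1% are rejected.
#'
#' @param oligo_volumes Two volumes in uL.
#' @param oligo_stocks Two stock concentration strings (molar units).
#' @param total Final annealing volume in uL.
#' @return Duplex concentration in uM.
#' @examples
#' anneal_concentration(c(5, 5), c("100 uM", "100 uM"), 50)  # 10
#' @export
anneal_concentration <- function(oligo_volumes, oligo_stocks, total) {
  if (length(oligo_volumes) != 2L || length(oligo_stocks) != 2L) {
    stop("exactly two complementary oligos are annealed")
  }
  if (any(oligo_volumes <= 0)) stop("oligo volumes must be > 0")
  st <- lapply(oligo_stocks, parse_conc)
  if (any(vapply(st, `[[`, character(1), "class") != "molar")) {
    stop("oligo stocks must be molar concentrations")
  }
  amounts <- vapply(seq_len(2L), function(i) st[[i]]$norm * oligo_volumes[i],
                    numeric(1))
  if (abs(amounts[1L] - amounts[2L]) / max(amounts) > 0.01) {
    stop("oligos are not equimolar (", sprintf("%.3g vs %.3g", amounts[1L],
         amounts[2L]), " nM*uL); mix complementary strands 1:1")
  }
  amounts[1L] / total / 1e3                   # nM*uL / uL -> nM -> uM
}

# ---- Protocol recipe presets -------------------------------------------
# The four standard mixes of the CRISPRdx workflow, as shipped defaults.

#' CRISPRdx mastermix recipe (20 uL, 40 nM Cas12a)
#'
#' CutSmart buffer 10x -> 1x, FAM reporter 10 uM -> 100 nM, crRNA
#' 10 uM -> 50 nM, EnGen LbCas12a 10 uM -> 40 nM, 2 uL target, water fill.
#' @inheritParams build_recipe
#' @param total Total volume in uL (default 20).
#' @return A `reaction_recipe`.
#' @export
crisprdx_mastermix <- function(total = 20, replicates = 1L, surplus = 0) {
  build_recipe(list(
    component("CutSmart Buffer", "10 x", "1 x"),
    component("FAM reporter", "10 uM", "100 nM"),
    component("crRNA", "10 uM", "50 nM"),
    component("EnGen LbCas12a", "10 uM", "40 nM"),
    component("target DNA", fixed_volume = 2,
              note = "added per well, not into the mastermix")),
    total = total, replicates = replicates, surplus = surplus)
}

#' PCR reaction recipe (15 uL, Q5 polymerase)
#'
#' Template 2 uL, Q5 2000 -> 20 U/mL, primers 10 uM -> 500 nM each, dNTP
#' 10 mM -> 200 uM, buffer 5x -> 1x, water fill.
#' @inheritParams crisprdx_mastermix
#' @param total Total volume in uL (default 15).
#' @return A `reaction_recipe`.
#' @export
pcr_recipe <- function(total = 15, replicates = 1L, surplus = 0) {
  build_recipe(list(
    component("DNA template", fixed_volume = 2, note = "0.5-10 ng"),
    component("Q5 DNA Polymerase", "2000 U/mL", "20 U/mL"),
    component("forward primer", "10 uM", "500 nM"),
    component("reverse primer", "10 uM", "500 nM"),
    component("dNTP", "10 mM", "200 uM"),
    component("Buffer", "5 x", "1 x")),
    total = total, replicates = replicates, surplus = surplus)
}

#' RPA reaction recipe (15 uL, isothermal amplification)
#'
#' Template 2 uL, reaction buffer 2x -> 1x, primers 100 uM -> 467 nM each,
#' dNTP 10 mM -> 900 uM, E-mix 10x -> 1x, core mix 20x -> 1x, MgOAc
#' 280 mM -> 14 mM (added last: it starts the reaction), water fill.
#' @inheritParams crisprdx_mastermix
#' @param total Total volume in uL (default 15).
#' @return A `reaction_recipe`.
#' @export
rpa_recipe <- function(total = 15, replicates = 1L, surplus = 0) {
  build_recipe(list(
    component("DNA template", fixed_volume = 2, note = "0.5-10 ng"),
    component("Reaction buffer", "2 x", "1 x"),
    component("Forward primer", "100 uM", "467 nM"),
    component("Reverse primer", "100 uM", "467 nM"),
    component("dNTP", "10 mM", "900 uM"),
    component("E-mix", "10 x", "1 x"),
    component("Core mix", "20 x", "1 x"),
    component("MgOAc", "280 mM", "14 mM",
              note = "add last, in the tube lid; starts the reaction")),
    total = total, replicates = replicates, surplus = surplus)
}

#' Annealing mix for 10 uM double-stranded targets (50 uL)
#'
#' 5 uL of each 100 uM complementary ssDNA oligo, 5 uL 10x buffer, water to
#' 50 uL; yields a 10 uM duplex.
#' @inheritParams crisprdx_mastermix
#' @param total Total volume in uL (default 50).
#' @return A `reaction_recipe` with the duplex concentration (uM) in
#'   `attr(x, "duplex_uM")`.
#' @export
annealing_recipe <- function(total = 50, replicates = 1L, surplus = 0) {
  out <- build_recipe(list(
    component("ssDNA oligo 1", fixed_volume = 5, note = "100 uM stock"),
    component("ssDNA oligo 2", fixed_volume = 5, note = "100 uM stock"),
    component("SuRE/Cut buffer M", "10 x", "1 x")),
    total = total, replicates = replicates, surplus = surplus)
  attr(out, "duplex_uM") <- anneal_concentration(c(5, 5),
                                                 c("100 uM", "100 uM"), total)
  out
}

#' Write a recipe as TSV
#' @param recipe A `reaction_recipe`.
#' @param path Output path or `""` for standard output.
#' @return Invisibly, `recipe`.
#' @export
write_recipe_tsv <- function(recipe, path = "") {
  df <- as.data.frame(recipe)
  df$volume <- sprintf("%.2f", df$volume)
  df$scaled <- sprintf("%.2f", df$scaled)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(recipe)
}
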