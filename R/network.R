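## Reaction-type time constants (hours). "custom" rows carry an explicit tau.
TAU_CLASSES <- c(
  "ligand-receptor" = 0.35,
  "transcription"   = 88,
  "translation"     = 1.13,
  "nfkb"            = 0.055,
  "signaling"       = 1,
  "combined"        = 90
)

#' Parse a Netflux-style reaction rule
#'
#' Grammar: `[!]ID ( & [!]ID )* => ID`. `!` marks an inhibiting input, `&`
#' declares an AND gate over the inputs of one reaction. Multiple rules with
#' the same target combine by OR in table order.
#'
#' @param rule rule string, e.g. `"GLU => AGE"`, `"!RhoRock => MLCP"`,
#'   `"Ca & !NO => MLCK"`.
#' @return list with `inputs` (data.frame of `species`, `sign`) and `target`.
#' @export
parse_rule <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1)
  sides <- strsplit(rule, "=>", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop(sprintf("rule '%s': expected exactly one '=>'", rule))
  }
  target <- trimws(sides[2])
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", target)) {
    stop(sprintf("rule '%s': malformed target '%s'", rule, target))
  }
  terms <- trimws(strsplit(sides[1], "&", fixed = TRUE)[[1]])
  if (length(terms) == 0 || any(!nzchar(terms))) {
    stop(sprintf("rule '%s': empty input term", rule))
  }
  sign <- ifelse(startsWith(terms, "!"), "inhibiting", "activating")
  species <- sub("^!", "", terms)
  bad <- !grepl("^[A-Za-z][A-Za-z0-9_]*$", species)
  if (any(bad)) {
    stop(sprintf("rule '%s': malformed input '%s'", rule, terms[bad][1]))
  }
  list(inputs = data.frame(species = species, sign = sign,
                           stringsAsFactors = FALSE),
       target = target)
}

#' Construct a logic-based ODE network specification
#'
#' @param species data.frame with columns `id`, `ymax`, `y0`, `tau_class`,
#'   `tau` (NA unless `tau_class == "custom"`), `compartment`.
#' @param reactions data.frame with columns `id`, `rule`, `W`, `n`, `EC50`.
#' @param variant `"disease"` or `"healthy"`. The healthy variant differs
#'   only in the sign of the Rho/Rock -> MLCP edge (activating instead of
#'   inhibiting), restoring the balance between stressed and relaxed actin.
#' @param stimulus id of the species driven by the external glucose weight.
#' @return object of class `fen_network`.
#' @export
network_spec <- function(species, reactions, variant = c("disease", "healthy"),
                         stimulus = "GLU") {
  variant <- match.arg(variant)
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)

  if (anyDuplicated(species$id)) {
    stop("duplicate species id: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  }
  known <- names(TAU_CLASSES)
  bad_class <- !(species$tau_class %in% c(known, "custom"))
  if (any(bad_class)) {
    stop("unknown tau_class: ",
         paste(unique(species$tau_class[bad_class]), collapse = ", "))
  }
  tau <- ifelse(species$tau_class == "custom",
                species$tau, TAU_CLASSES[species$tau_class])
  if (any(is.na(tau) | tau <= 0)) stop("every species needs tau > 0")
  species$tau <- as.numeric(tau)
  if (any(species$y0 < 0 | species$y0 > species$ymax)) {
    stop("species initial values must satisfy 0 <= y0 <= ymax")
  }
  if (!stimulus %in% species$id) {
    stop(sprintf("stimulus species '%s' is not declared", stimulus))
  }

  if (anyDuplicated(reactions$id)) stop("duplicate reaction id")
  parsed <- lapply(reactions$rule, parse_rule)
  reactions$target <- vapply(parsed, `[[`, character(1), "target")
  all_named <- unique(c(unlist(lapply(parsed, function(p) p$inputs$species)),
                        reactions$target))
  undeclared <- setdiff(all_named, species$id)
  if (length(undeclared)) {
    stop("rule references undeclared species: ",
         paste(undeclared, collapse = ", "))
  }
  if (any(reactions$target == stimulus)) {
    stop("the stimulus species cannot be the target of a reaction; it is ",
         "driven by the glucose schedule")
  }
  hill_constants(reactions$n, reactions$EC50)  # validates n, EC50
  if (any(reactions$W < 0 | reactions$W > 1)) {
    stop("reaction weights must lie in [0, 1]")
  }

  net <- structure(list(species = species, reactions = reactions,
                        inputs = lapply(parsed, `[[`, "inputs"),
                        variant = variant, stimulus = stimulus),
                   class = "fen_network")
  if (variant == "healthy") net <- flip_mlcp_edge(net) else net
}

## The healthy variant flips the single Rho/Rock -> MLCP edge from inhibiting
## to activating; nothing else differs between the two variants.
flip_mlcp_edge <- function(net) {
  hit <- which(net$reactions$target == "MLCP" &
                 vapply(net$inputs, function(inp) {
                   nrow(inp) == 1 && inp$species == "RhoRock"
                 }, logical(1)))
  if (length(hit) != 1) {
    stop("healthy variant requires exactly one RhoRock => MLCP reaction")
  }
  net$inputs[[hit]]$sign <- "activating"
  net$reactions$rule[hit] <- "RhoRock => MLCP"
  net
}

#' Switch a network between the disease and healthy variants
#'
#' @param net a `fen_network`.
#' @param variant `"disease"` or `"healthy"`.
#' @return the network with the Rho/Rock -> MLCP edge sign set accordingly.
#' @export
network_variant <- function(net, variant = c("disease", "healthy")) {
  variant <- match.arg(variant)
  stopifnot(inherits(net, "fen_network"))
  if (identical(net$variant, variant)) return(net)
  hit <- which(net$reactions$target == "MLCP" &
                 vapply(net$inputs, function(inp) {
                   nrow(inp) == 1 && inp$species == "RhoRock"
                 }, logical(1)))
  if (length(hit) != 1) stop("network lacks a unique RhoRock => MLCP edge")
  if (variant == "healthy") {
    net$inputs[[hit]]$sign <- "activating"
    net$reactions$rule[hit] <- "RhoRock => MLCP"
  } else {
    net$inputs[[hit]]$sign <- "inhibiting"
    net$reactions$rule[hit] <- "!RhoRock => MLCP"
  }
  net$variant <- variant
  net
}

#' The macrophage--glomerular-endothelial-cell signaling network
#'
#' Reads the network fixture shipped with the package: 34 species spanning a
#' macrophage compartment (glucose-driven AGE/RAGE/NADPH-oxidase/ROS arm and
#' the IL-1 receptor / NF-kB / VEGF-A production arm) and a GEC compartment
#' (AGE/RAGE/ROS/NF-kB arm secreting IL-1beta, VEGF receptor signaling
#' through PLC-gamma/calcium and PI3K/AKT/eNOS/NO, Rho/Rock regulation of the
#' myosin-light-chain phosphorylation cycle, and stressed/relaxed actin).
#' Glucose (`GLU`) is the single external stimulus. The fixture is a
#' reconstruction of the published topology from the network figure and the
#' interactions named in the accompanying text, with documented default
#' parameters (`W = 1`, `n = 1.4`, `EC50 = 0.5`, `y0 = 0`, `ymax = 1`, tau by
#' reaction-type class; tau_pMLC = 400 h); each fixture row records whether
#' its values are defaults or taken from printed sources.
#'
#' @inheritParams network_spec
#' @return a `fen_network`.
#' @export
fen_network <- function(variant = c("disease", "healthy")) {
  variant <- match.arg(variant)
  dir <- system.file("extdata", package = "fenestra")
  read_network(file.path(dir, "species.tsv"),
               file.path(dir, "reactions.tsv"),
               variant = variant)
}

#' @export
print.fen_network <- function(x, ...) {
  cat(sprintf("Logic-based ODE network: %d species, %d reactions (%s variant)\n",
              nrow(x$species), nrow(x$reactions), x$variant))
  cat(sprintf("Stimulus: %s; compartments: %s\n", x$stimulus,
              paste(unique(x$species$compartment), collapse = ", ")))
  invisible(x)
}
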