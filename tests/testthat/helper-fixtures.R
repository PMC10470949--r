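# Small models built in code, shared across test files.

# Linear chain: uptake -> A -> B -> export, bottleneck 10 at the uptake.
chain_model <- function(ub_in = 10) {
  metabolic_model(
    id = "chain",
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"),
                             compartment = "c", stringsAsFactors = FALSE),
    reactions = list(
      reaction("R_in", stoichiometry = c(A = 1), lb = 0, ub = ub_in),
      reaction("R_mid", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
      reaction("R_out", stoichiometry = c(B = -1), lb = 0, ub = 1000)
    ),
    objective = "R_out"
  )
}

# Two equivalent parallel paths A -> B carrying different weights.
two_path_model <- function() {
  metabolic_model(
    id = "two_path",
    metabolites = data.frame(id = c("A", "B"), name = c("A", "B"),
                             compartment = "c", stringsAsFactors = FALSE),
    reactions = list(
      reaction("R_in", stoichiometry = c(A = 1), lb = 0, ub = 10),
      reaction("P1", stoichiometry = c(A = -1, B = 1), gpr = "G1"),
      reaction("P2", stoichiometry = c(A = -1, B = 1), gpr = "G2"),
      reaction("R_out", stoichiometry = c(B = -1), lb = 0, ub = 1000)
    ),
    objective = "R_out"
  )
}

# Fully determined polytope: every feasible flux vector is (2, 2).
fixed_flux_model <- function() {
  metabolic_model(
    id = "fixed",
    metabolites = data.frame(id = "A", name = "A", compartment = "c",
                             stringsAsFactors = FALSE),
    reactions = list(
      reaction("R1", stoichiometry = c(A = 1), lb = 2, ub = 2),
      reaction("R2", stoichiometry = c(A = -1), lb = 0, ub = 10)
    ),
    objective = "R2"
  )
}

# One-dimensional box: v1 = v2, both in [0, 1].
box_model <- function() {
  metabolic_model(
    id = "box",
    metabolites = data.frame(id = "A", name = "A", compartment = "c",
                             stringsAsFactors = FALSE),
    reactions = list(
      reaction("R1", stoichiometry = c(A = 1), lb = 0, ub = 1),
      reaction("R2", stoichiometry = c(A = -1), lb = 0, ub = 1)
    ),
    objective = "R2"
  )
}

# The package's JSON dialect: 2 metabolites, 3 reactions, 1 GPR.
toy_json_string <- function() {
  '{
    "id": "toy",
    "metabolites": [
      {"id": "m1", "name": "met one", "compartment": "c"},
      {"id": "m2", "name": "met two", "compartment": "c"}
    ],
    "reactions": [
      {"id": "r1", "name": "in", "stoichiometry": {"m1": 1}, "lb": 0, "ub": 10},
      {"id": "r2", "name": "conv", "stoichiometry": {"m1": -1, "m2": 1},
       "lb": 0, "ub": 1000, "gpr": "(G1 and G2) or G3",
       "subsystem": "Conversion"},
      {"id": "r3", "name": "out", "stoichiometry": {"m2": -1}, "lb": 0, "ub": 1000}
    ],
    "genes": ["G1", "G2", "G3"],
    "objective": "r3"
  }'
}

# Minimal SBML L3 + FBC v2 + groups document mirroring the JSON toy.
toy_sbml_string <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1" ',
    'level="3" version="1" fbc:required="false" groups:required="false">\n',
    '<model id="toy_sbml" fbc:strict="true">\n',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>\n',
    '<listOfSpecies>\n',
    '<species id="m1" name="met one" compartment="c" constant="false" ',
    'hasOnlySubstanceUnits="false" boundaryCondition="false"/>\n',
    '<species id="m2" name="met two" compartment="c" constant="false" ',
    'hasOnlySubstanceUnits="false" boundaryCondition="false"/>\n',
    '</listOfSpecies>\n',
    '<listOfParameters>\n',
    '<parameter id="lb_zero" value="0" constant="true"/>\n',
    '<parameter id="ub_ten" value="10" constant="true"/>\n',
    '<parameter id="ub_big" value="1000" constant="true"/>\n',
    '</listOfParameters>\n',
    '<fbc:listOfGeneProducts>\n',
    '<fbc:geneProduct fbc:id="gp1" fbc:label="G1"/>\n',
    '<fbc:geneProduct fbc:id="gp2" fbc:label="G2"/>\n',
    '<fbc:geneProduct fbc:id="gp3" fbc:label="G3"/>\n',
    '</fbc:listOfGeneProducts>\n',
    '<listOfReactions>\n',
    '<reaction id="r1" reversible="false" fast="false" ',
    'fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">\n',
    '<listOfProducts><speciesReference species="m1" stoichiometry="1" ',
    'constant="true"/></listOfProducts>\n',
    '</reaction>\n',
    '<reaction id="r2" reversible="false" fast="false" ',
    'fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
    '<listOfReactants><speciesReference species="m1" stoichiometry="1" ',
    'constant="true"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="m2" stoichiometry="1" ',
    'constant="true"/></listOfProducts>\n',
    '<fbc:geneProductAssociation>\n',
    '<fbc:or>\n',
    '<fbc:and>\n',
    '<fbc:geneProductRef fbc:geneProduct="gp1"/>\n',
    '<fbc:geneProductRef fbc:geneProduct="gp2"/>\n',
    '</fbc:and>\n',
    '<fbc:geneProductRef fbc:geneProduct="gp3"/>\n',
    '</fbc:or>\n',
    '</fbc:geneProductAssociation>\n',
    '</reaction>\n',
    '<reaction id="r3" reversible="false" fast="false" ',
    'fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
    '<listOfReactants><speciesReference species="m2" stoichiometry="1" ',
    'constant="true"/></listOfReactants>\n',
    '</reaction>\n',
    '</listOfReactions>\n',
    '<fbc:listOfObjectives fbc:activeObjective="obj">\n',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">\n',
    '<fbc:listOfFluxObjectives>\n',
    '<fbc:fluxObjective fbc:reaction="r3" fbc:coefficient="1"/>\n',
    '</fbc:listOfFluxObjectives>\n',
    '</fbc:objective>\n',
    '</fbc:listOfObjectives>\n',
    '<groups:listOfGroups>\n',
    '<groups:group groups:id="g1" groups:kind="partonomy" ',
    'groups:name="Conversion">\n',
    '<groups:listOfMembers>\n',
    '<groups:member groups:idRef="r2"/>\n',
    '</groups:listOfMembers>\n',
    '</groups:group>\n',
    '</groups:listOfGroups>\n',
    '</model>\n</sbml>\n'
  )
}
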