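# Hand-built fixture documents used across the suite.

SBML_NS_T <- "http://www.sbml.org/sbml/level2/version4"
CELLML_NS_T <- "http://www.cellml.org/cellml/1.0#"

fix_sbml_small <- function() {
  # 2 species, 1 reaction, 1 compartment, 1 parameter
  paste0('<sbml xmlns="', SBML_NS_T, '" level="2" version="4">
  <model id="mini" name="tiny model">
    <listOfCompartments><compartment id="c1" size="1"/></listOfCompartments>
    <listOfSpecies>
      <species id="S1" compartment="c1" initialConcentration="1"/>
      <species id="S2" compartment="c1" initialConcentration="0.5"/>
    </listOfSpecies>
    <listOfParameters><parameter id="k1" value="0.1"/></listOfParameters>
    <listOfReactions>
      <reaction id="R1" reversible="false">
        <listOfReactants><speciesReference species="S1"/></listOfReactants>
        <listOfProducts><speciesReference species="S2"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>')
}

fix_cellml_small <- function() {
  # 2 components, 3 variables, 1 units definition
  paste0('<model xmlns="', CELLML_NS_T, '" name="cm">
  <units name="per_s"><unit units="second" exponent="-1"/></units>
  <component name="A">
    <variable name="x" units="per_s" initial_value="1"/>
    <variable name="y" units="per_s"/>
  </component>
  <component name="B"><variable name="z" units="per_s"/></component>
  <connection>
    <map_components component_1="A" component_2="B"/>
    <map_variables variable_1="x" variable_2="z"/>
  </connection>
</model>')
}

parse_fix <- function(txt, model_id = "FIX", version_id = "1",
                      timestamp = "2005-04-11") {
  parse_model(txt, model_id, version_id, timestamp)
}

# fixture with an attribute-free reaction subtree of known element count,
# for the triggered-delete example
fix_sbml_plain_reaction <- function() {
  paste0('<sbml xmlns="', SBML_NS_T, '" level="2" version="4">
  <model id="pr">
    <listOfSpecies><species id="S1"/></listOfSpecies>
    <listOfReactions>
      <reaction>
        <listOfReactants><speciesReference/></listOfReactants>
        <listOfProducts><speciesReference/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>')
}

op_key <- function(op) paste(op$op_type, op$entity_kind, op$old_path,
                             op$new_path, op$triggered)
op_path_key <- function(op) paste(op$op_type, op$old_path, op$new_path)
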