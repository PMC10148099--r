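<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy3" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="metabolite A" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="B" name="metabolite B" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
      <parameter id="ten" value="10" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" name="A source" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_AB" name="A to B" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Toy pathway</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_GAB"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_B" name="B sink" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_GAB" fbc:label="GAB"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
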