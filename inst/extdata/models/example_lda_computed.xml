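<?xml version="1.0" encoding="UTF-8"?>
<qsar_model type="lda" version="1">
  <metadata id="example-class-lda" endpoint="synthetic weight class" units="" group="Examples" subgroup="Synthetic class" citation="synthetic example model shipped with the package"/>
  <descriptors>
    <descriptor name="molecular_weight" source="computed"></descriptor>
    <descriptor name="heavy_atom_count" source="computed"></descriptor>
    <descriptor name="ring_count" source="computed"></descriptor>
  </descriptors>
  <training>
    <chemical id="methane" smiles="C">
      <value d="molecular_weight">16.042459999999998</value>
      <value d="heavy_atom_count">1</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="ethane" smiles="CC">
      <value d="molecular_weight">30.069040000000001</value>
      <value d="heavy_atom_count">2</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="propane" smiles="CCC">
      <value d="molecular_weight">44.095619999999997</value>
      <value d="heavy_atom_count">3</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="butane" smiles="CCCC">
      <value d="molecular_weight">58.122199999999999</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="isobutane" smiles="CC(C)C">
      <value d="molecular_weight">58.122200000000007</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="pentane" smiles="CCCCC">
      <value d="molecular_weight">72.148780000000002</value>
      <value d="heavy_atom_count">5</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="cyclohexane" smiles="C1CCCCC1">
      <value d="molecular_weight">84.159479999999988</value>
      <value d="heavy_atom_count">6</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="benzene" smiles="c1ccccc1">
      <value d="molecular_weight">78.111840000000001</value>
      <value d="heavy_atom_count">6</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="toluene" smiles="Cc1ccccc1">
      <value d="molecular_weight">92.138420000000011</value>
      <value d="heavy_atom_count">7</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="phenol" smiles="Oc1ccccc1">
      <value d="molecular_weight">94.111240000000009</value>
      <value d="heavy_atom_count">7</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="methanol" smiles="CO">
      <value d="molecular_weight">32.04186</value>
      <value d="heavy_atom_count">2</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="ethanol" smiles="CCO">
      <value d="molecular_weight">46.068439999999995</value>
      <value d="heavy_atom_count">3</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="acetic_acid" smiles="CC(=O)O">
      <value d="molecular_weight">60.051960000000001</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="acetone" smiles="CC(C)=O">
      <value d="molecular_weight">58.079140000000002</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="ethylamine" smiles="CCN">
      <value d="molecular_weight">45.083680000000001</value>
      <value d="heavy_atom_count">3</value>
      <value d="ring_count">0</value>
      <endpoint>light</endpoint>
    </chemical>
    <chemical id="diethyl_ether" smiles="CCOCC">
      <value d="molecular_weight">74.121600000000001</value>
      <value d="heavy_atom_count">5</value>
      <value d="ring_count">0</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="chloroform" smiles="ClC(Cl)Cl">
      <value d="molecular_weight">119.37764000000001</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="chlorobenzene" smiles="Clc1ccccc1">
      <value d="molecular_weight">112.55690000000003</value>
      <value d="heavy_atom_count">7</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="pyridine" smiles="c1ccncc1">
      <value d="molecular_weight">79.099900000000005</value>
      <value d="heavy_atom_count">6</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="naphthalene" smiles="c1ccc2ccccc2c1">
      <value d="molecular_weight">128.17052000000001</value>
      <value d="heavy_atom_count">10</value>
      <value d="ring_count">2</value>
      <endpoint>heavy</endpoint>
    </chemical>
    <chemical id="styrene" smiles="C=Cc1ccccc1">
      <value d="molecular_weight">104.14912000000002</value>
      <value d="heavy_atom_count">8</value>
      <value d="ring_count">1</value>
      <endpoint>heavy</endpoint>
    </chemical>
  </training>
  <lda_settings event_class="heavy" percentile="0.94999999999999996"/>
</qsar_model>
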