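<?xml version="1.0" encoding="UTF-8"?>
<qsar_model type="mlr" version="1">
  <metadata id="example-logk-mlr" endpoint="synthetic log K" units="log units" group="Examples" subgroup="Synthetic log K" citation="synthetic example model shipped with the package"/>
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
      <endpoint>0.23200000000000001</endpoint>
    </chemical>
    <chemical id="ethane" smiles="CC">
      <value d="molecular_weight">30.069040000000001</value>
      <value d="heavy_atom_count">2</value>
      <value d="ring_count">0</value>
      <endpoint>0.61499999999999999</endpoint>
    </chemical>
    <chemical id="propane" smiles="CCC">
      <value d="molecular_weight">44.095619999999997</value>
      <value d="heavy_atom_count">3</value>
      <value d="ring_count">0</value>
      <endpoint>0.67400000000000004</endpoint>
    </chemical>
    <chemical id="butane" smiles="CCCC">
      <value d="molecular_weight">58.122199999999999</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>0.98740000000000006</endpoint>
    </chemical>
    <chemical id="isobutane" smiles="CC(C)C">
      <value d="molecular_weight">58.122200000000007</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>1.3686</endpoint>
    </chemical>
    <chemical id="pentane" smiles="CCCCC">
      <value d="molecular_weight">72.148780000000002</value>
      <value d="heavy_atom_count">5</value>
      <value d="ring_count">0</value>
      <endpoint>1.3421000000000001</endpoint>
    </chemical>
    <chemical id="cyclohexane" smiles="C1CCCCC1">
      <value d="molecular_weight">84.159479999999988</value>
      <value d="heavy_atom_count">6</value>
      <value d="ring_count">1</value>
      <endpoint>1.7408999999999999</endpoint>
    </chemical>
    <chemical id="benzene" smiles="c1ccccc1">
      <value d="molecular_weight">78.111840000000001</value>
      <value d="heavy_atom_count">6</value>
      <value d="ring_count">1</value>
      <endpoint>1.5454000000000001</endpoint>
    </chemical>
    <chemical id="toluene" smiles="Cc1ccccc1">
      <value d="molecular_weight">92.138420000000011</value>
      <value d="heavy_atom_count">7</value>
      <value d="ring_count">1</value>
      <endpoint>1.7352000000000001</endpoint>
    </chemical>
    <chemical id="phenol" smiles="Oc1ccccc1">
      <value d="molecular_weight">94.111240000000009</value>
      <value d="heavy_atom_count">7</value>
      <value d="ring_count">1</value>
      <endpoint>1.6211</endpoint>
    </chemical>
    <chemical id="methanol" smiles="CO">
      <value d="molecular_weight">32.04186</value>
      <value d="heavy_atom_count">2</value>
      <value d="ring_count">0</value>
      <endpoint>0.51639999999999997</endpoint>
    </chemical>
    <chemical id="ethanol" smiles="CCO">
      <value d="molecular_weight">46.068439999999995</value>
      <value d="heavy_atom_count">3</value>
      <value d="ring_count">0</value>
      <endpoint>0.87880000000000003</endpoint>
    </chemical>
    <chemical id="acetic_acid" smiles="CC(=O)O">
      <value d="molecular_weight">60.051960000000001</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>0.98999999999999999</endpoint>
    </chemical>
    <chemical id="acetone" smiles="CC(C)=O">
      <value d="molecular_weight">58.079140000000002</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>1.1529</endpoint>
    </chemical>
    <chemical id="ethylamine" smiles="CCN">
      <value d="molecular_weight">45.083680000000001</value>
      <value d="heavy_atom_count">3</value>
      <value d="ring_count">0</value>
      <endpoint>0.74380000000000002</endpoint>
    </chemical>
    <chemical id="diethyl_ether" smiles="CCOCC">
      <value d="molecular_weight">74.121600000000001</value>
      <value d="heavy_atom_count">5</value>
      <value d="ring_count">0</value>
      <endpoint>1.5137</endpoint>
    </chemical>
    <chemical id="chloroform" smiles="ClC(Cl)Cl">
      <value d="molecular_weight">119.37764000000001</value>
      <value d="heavy_atom_count">4</value>
      <value d="ring_count">0</value>
      <endpoint>2.0771999999999999</endpoint>
    </chemical>
    <chemical id="chlorobenzene" smiles="Clc1ccccc1">
      <value d="molecular_weight">112.55690000000003</value>
      <value d="heavy_atom_count">7</value>
      <value d="ring_count">1</value>
      <endpoint>2.1815000000000002</endpoint>
    </chemical>
    <chemical id="pyridine" smiles="c1ccncc1">
      <value d="molecular_weight">79.099900000000005</value>
      <value d="heavy_atom_count">6</value>
      <value d="ring_count">1</value>
      <endpoint>1.3776999999999999</endpoint>
    </chemical>
    <chemical id="naphthalene" smiles="c1ccc2ccccc2c1">
      <value d="molecular_weight">128.17052000000001</value>
      <value d="heavy_atom_count">10</value>
      <value d="ring_count">2</value>
      <endpoint>2.2242000000000002</endpoint>
    </chemical>
    <chemical id="styrene" smiles="C=Cc1ccccc1">
      <value d="molecular_weight">104.14912000000002</value>
      <value d="heavy_atom_count">8</value>
      <value d="ring_count">1</value>
      <endpoint>1.8998999999999999</endpoint>
    </chemical>
  </training>
  <coefficients intercept="-0.05439095878181878">
    <coef d="molecular_weight">0.016860785191799597</coef>
    <coef d="heavy_atom_count">0.043081350780298226</coef>
    <coef d="ring_count">-0.093890958065842328</coef>
  </coefficients>
</qsar_model>
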