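<?xml version="1.0" encoding="UTF-8"?>
<qsar_model type="mlr" version="1">
  <metadata id="example-supplied-mlr" endpoint="synthetic endpoint" units="log units" group="Examples" subgroup="Synthetic supplied" citation="synthetic example model shipped with the package"/>
  <descriptors>
    <descriptor name="d1" source="supplied"></descriptor>
    <descriptor name="d2" source="supplied"></descriptor>
  </descriptors>
  <training>
    <chemical id="chem001">
      <value d="d1">-1.480567594919364</value>
      <value d="d2">0.2236414153762733</value>
      <endpoint>-0.15194194647325271</endpoint>
    </chemical>
    <chemical id="chem002">
      <value d="d1">1.5771694715586291</value>
      <value d="d2">2.0072014569454364</value>
      <endpoint>3.4283780383119584</endpoint>
    </chemical>
    <chemical id="chem003">
      <value d="d1">-0.95674447908426852</value>
      <value d="d2">1.0119791180671451</value>
      <endpoint>1.6333692659407322</endpoint>
    </chemical>
    <chemical id="chem004">
      <value d="d1">-0.92000524755864099</value>
      <value d="d2">-0.30245924516826544</value>
      <endpoint>-1.8180901489204306</endpoint>
    </chemical>
    <chemical id="chem005">
      <value d="d1">-1.9976420969313426</value>
      <value d="d2">-1.0252448390136608</value>
      <endpoint>-2.3313905921509184</endpoint>
    </chemical>
    <chemical id="chem006">
      <value d="d1">-0.27229604424922993</value>
      <value d="d2">-0.26738482999428187</value>
      <endpoint>0.90978504787908676</endpoint>
    </chemical>
    <chemical id="chem007">
      <value d="d1">-0.31534871146778415</value>
      <value d="d2">-0.19910566111476233</value>
      <endpoint>-0.49150765521191875</endpoint>
    </chemical>
    <chemical id="chem008">
      <value d="d1">-0.62825523651753756</value>
      <value d="d2">0.13112259542437482</value>
      <endpoint>0.69286521827408243</endpoint>
    </chemical>
    <chemical id="chem009">
      <value d="d1">-0.10646388487209443</value>
      <value d="d2">0.14579989554370096</value>
      <endpoint>1.7707893679717834</endpoint>
    </chemical>
    <chemical id="chem010">
      <value d="d1">0.42801480220235449</value>
      <value d="d2">0.36206472111722926</value>
      <endpoint>1.2974804125652897</endpoint>
    </chemical>
    <chemical id="chem011">
      <value d="d1">-0.77771958214744541</value>
      <value d="d2">0.67398116380047512</value>
      <endpoint>0.85357666947903466</endpoint>
    </chemical>
    <chemical id="chem012">
      <value d="d1">-1.2938822976136173</value>
      <value d="d2">2.0720357681505686</value>
      <endpoint>1.6654828941030566</endpoint>
    </chemical>
    <chemical id="chem013">
      <value d="d1">-0.77956650805942906</value>
      <value d="d2">-0.54102864906147552</value>
      <endpoint>0.13623209060552705</endpoint>
    </chemical>
    <chemical id="chem014">
      <value d="d1">0.011951758565298396</value>
      <value d="d2">-1.0704921583121028</value>
      <endpoint>1.9617944420199649</endpoint>
    </chemical>
    <chemical id="chem015">
      <value d="d1">-0.1524162378221677</value>
      <value d="d2">-0.37245673227827275</value>
      <endpoint>-0.57576303255349992</endpoint>
    </chemical>
    <chemical id="chem016">
      <value d="d1">-0.70346425447864236</value>
      <value d="d2">-0.48514135478827575</value>
      <endpoint>0.54604649662826943</endpoint>
    </chemical>
    <chemical id="chem017">
      <value d="d1">1.1888791562756698</value>
      <value d="d2">0.27478417847570896</value>
      <endpoint>3.0029130787029259</endpoint>
    </chemical>
    <chemical id="chem018">
      <value d="d1">0.3405122708491875</value>
      <value d="d2">-0.47951256158230038</value>
      <endpoint>-0.4532730876834774</endpoint>
    </chemical>
    <chemical id="chem019">
      <value d="d1">0.50696817225916591</value>
      <value d="d2">0.7981053261253751</value>
      <endpoint>2.055034776326667</endpoint>
    </chemical>
    <chemical id="chem020">
      <value d="d1">-0.29330514908141092</value>
      <value d="d2">-1.0044512023887167</value>
      <endpoint>0.016448244966700276</endpoint>
    </chemical>
  </training>
  <coefficients intercept="0.93910714768668113">
    <coef d="d1">0.93641293528958713</coef>
    <coef d="d2">0.80322780891984757</coef>
  </coefficients>
</qsar_model>
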