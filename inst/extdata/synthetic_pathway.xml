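<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:synthetic" org="hsa" number="00000" title="synthetic demo pathway">
  <entry id="1" name="hsa:1001" type="gene">
    <graphics name="GENA, ALIASA" type="rectangle"/>
  </entry>
  <entry id="2" name="hsa:1002" type="gene">
    <graphics name="GENB" type="rectangle"/>
  </entry>
  <entry id="3" name="hsa:1003" type="gene">
    <graphics name="GENC" type="rectangle"/>
  </entry>
  <entry id="4" name="hsa:1004 hsa:1005" type="gene">
    <graphics name="GEND1, GEND2, ..." type="rectangle"/>
  </entry>
  <entry id="5" name="hsa:1006" type="gene">
    <graphics name="GENE5" type="rectangle"/>
  </entry>
  <entry id="6" name="cpd:C00165" type="compound">
    <graphics name="C00165" type="rectangle"/>
  </entry>
  <entry id="7" name="undefined" type="group">
    <component id="2"/>
    <component id="3"/>
  </entry>
  <relation entry1="1" entry2="7" type="PPrel">
    <subtype name="activation" value=""/>
  </relation>
  <relation entry1="2" entry2="5" type="PPrel">
    <subtype name="binding/association" value=""/>
  </relation>
  <relation entry1="5" entry2="4" type="PPrel">
    <subtype name="inhibition" value=""/>
  </relation>
  <relation entry1="4" entry2="1" type="PPrel">
    <subtype name="phosphorylation" value=""/>
  </relation>
</pathway>
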