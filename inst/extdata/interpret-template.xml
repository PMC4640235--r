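<?xml version="1.0" encoding="UTF-8"?>
<PipelineConfig>
  <SetReference enabled="false" reference="4.75"/>
  <Apodize enabled="false" shape="Lorentzian" linewidth="1"/>
  <WaterFiltering enabled="false" lorentzians="10">
    <Region upper="5.0999999999999996" lower="4.2999999999999998"/>
  </WaterFiltering>
  <BaselineCorrection enabled="false"/>
  <ChangePoints enabled="true" points="512">
    <Range upper="7.0999999999999996" lower="-2.7000000000000002"/>
  </ChangePoints>
  <SetToZero enabled="true">
    <Region upper="1000" lower="7.1001000000000003"/>
    <Region upper="-2.7000999999999999" lower="-1000"/>
  </SetToZero>
  <Normalization enabled="true" type="l2"/>
  <AlignmentCorrection enabled="true" brainPreset="false">
    <Peak ppm="3.21"/>
    <Peak ppm="3.0299999999999998"/>
    <Peak ppm="2.0099999999999998"/>
    <Noise upper="-0.69999999999999996" lower="-2.7000000000000002"/>
  </AlignmentCorrection>
  <OutputRange enabled="true">
    <Range upper="7.0999999999999996" lower="-2.7000000000000002"/>
  </OutputRange>
  <SnrNoise>
    <Range upper="-0.69999999999999996" lower="-2.7000000000000002"/>
  </SnrNoise>
</PipelineConfig>
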