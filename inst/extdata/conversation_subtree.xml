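<?xml version="1.0" encoding="UTF-8"?>
<!-- Small extract of the ICF Activities and Participation component
     (Communication chapter): the Conversation and Discussion categories
     with their published subcategories, used for relationship-suggestion
     and annotated-export examples. -->
<ClaML version="2.0.0">
  <Title name="Activities and Participation extract" version="0.1"/>
  <Class code="d3" kind="chapter">
    <SubClass code="d350-d369"/>
    <Rubric kind="preferred"><Label>Communication</Label></Rubric>
  </Class>
  <Class code="d350-d369" kind="block">
    <SuperClass code="d3"/>
    <SubClass code="d350"/>
    <SubClass code="d355"/>
    <Rubric kind="preferred"><Label>Conversation and use of communication devices and techniques</Label></Rubric>
  </Class>
  <Class code="d350" kind="category">
    <SuperClass code="d350-d369"/>
    <SubClass code="d3500"/>
    <SubClass code="d3501"/>
    <SubClass code="d3502"/>
    <SubClass code="d3503"/>
    <SubClass code="d3504"/>
    <Rubric kind="preferred"><Label>Conversation</Label></Rubric>
    <Rubric kind="definition"><Label>Starting, sustaining and ending an interchange of thoughts and ideas.</Label></Rubric>
  </Class>
  <Class code="d3500" kind="category">
    <SuperClass code="d350"/>
    <Rubric kind="preferred"><Label>Starting a conversation</Label></Rubric>
  </Class>
  <Class code="d3501" kind="category">
    <SuperClass code="d350"/>
    <Rubric kind="preferred"><Label>Sustaining a conversation</Label></Rubric>
  </Class>
  <Class code="d3502" kind="category">
    <SuperClass code="d350"/>
    <Rubric kind="preferred"><Label>Ending a conversation</Label></Rubric>
  </Class>
  <Class code="d3503" kind="category">
    <SuperClass code="d350"/>
    <Rubric kind="preferred"><Label>Conversing with one person</Label></Rubric>
  </Class>
  <Class code="d3504" kind="category">
    <SuperClass code="d350"/>
    <Rubric kind="preferred"><Label>Conversing with many people</Label></Rubric>
  </Class>
  <Class code="d355" kind="category">
    <SuperClass code="d350-d369"/>
    <SubClass code="d3550"/>
    <SubClass code="d3551"/>
    <Rubric kind="preferred"><Label>Discussion</Label></Rubric>
  </Class>
  <Class code="d3550" kind="category">
    <SuperClass code="d355"/>
    <Rubric kind="preferred"><Label>Discussion with one person</Label></Rubric>
  </Class>
  <Class code="d3551" kind="category">
    <SuperClass code="d355"/>
    <Rubric kind="preferred"><Label>Discussion with many people</Label></Rubric>
  </Class>
</ClaML>
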